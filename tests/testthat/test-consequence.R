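test_that("canonical stopgain, splice and synonymous SNVs classify correctly", {
  hp <- hand_gene_plus()
  tx <- hp$gene$transcripts[[1L]]
  # CGA (codon 2, exon 1) -> TGA
  v <- data.frame(chrom = "chrT", pos = 14L, ref = "C", alt = "T",
                  vclass = "SNV", key = "chrT:14:C:T")
  r <- classify_snv(v, tx, hp$gene, hp$reference)
  expect_equal(r$category, "stopgain")
  expect_equal(r$exon_index, 1L)
  expect_false(r$is_terminal_coding_exon)
  # intron acceptor -2 position (e-1 of intron 17..30)
  v$pos <- 29L
  expect_equal(classify_snv(v, tx, hp$gene, hp$reference)$category,
               "splice_essential")
  # CAA -> CAG keeps glutamine
  v2 <- data.frame(chrom = "chrT", pos = 33L, ref = "A", alt = "G",
                   vclass = "SNV", key = "chrT:33:A:G")
  expect_equal(classify_snv(v2, tx, hp$gene, hp$reference)$category,
               "synonymous")
  # losing the terminal stop is not a stopgain (TAA -> GAA)
  v3 <- data.frame(chrom = "chrT", pos = 54L, ref = "T", alt = "G",
                   vclass = "SNV", key = "chrT:54:T:G")
  expect_equal(classify_snv(v3, tx, hp$gene, hp$reference)$category,
               "other")
  # stop-to-stop substitution is synonymous (TAA -> TAG)
  v4 <- data.frame(chrom = "chrT", pos = 56L, ref = "A", alt = "G",
                   vclass = "SNV", key = "chrT:56:A:G")
  expect_equal(classify_snv(v4, tx, hp$gene, hp$reference)$category,
               "synonymous")
})

test_that("minus-strand SNVs are classified in transcript orientation", {
  hm <- hand_gene_minus()
  tx <- hm$gene$transcripts[[1L]]
  # genomic position of CDS base 6 (codon 2 pos 3, CGA); CDS index 6 maps
  # to genomic position 51 on the minus strand (exons 51..56 hold CDS 1..6)
  # mutate codon CGA -> TGA: CDS base 4 C>T, genomic pos 53, G>A on plus
  v <- data.frame(chrom = "chrT", pos = 53L, ref = "G", alt = "A",
                  vclass = "SNV", key = "chrT:53:G:A")
  r <- classify_snv(v, tx, hm$gene, hm$reference)
  expect_equal(r$category, "stopgain")
  expect_equal(r$exon_index, 1L)
})

test_that("SNV classification equals the mutate-and-translate oracle on
           every planted variant and random exonic substitutions", {
  sim <- shared_sim()
  genome <- sim$genome
  snvs <- sim$planted$variants[sim$planted$variants$vclass == "SNV", ]
  checked <- 0L
  for (i in seq_len(nrow(snvs))) {
    v <- snvs[i, ]
    for (g in genome$models) {
      if (g$chrom != v$chrom) next
      chromseq <- genome$reference[[g$chrom]]
      for (tx in g$transcripts) {
        span <- range(tx$exons)
        if (v$pos < min(tx$exons$start) || v$pos > max(tx$exons$end)) next
        got <- classify_snv(v, tx, g, genome$reference)$category
        want <- oracle_snv_category(v$pos, v$alt, tx, g$strand, chromseq)
        expect_identical(got, want,
                         info = paste(v$key, tx$transcript_id))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 20L)
  # random substitutions across random genes
  set.seed(77)
  for (rep in 1:300) {
    g <- genome$models[[sample(length(genome$models), 1L)]]
    chromseq <- genome$reference[[g$chrom]]
    tx <- g$transcripts[[sample(length(g$transcripts), 1L)]]
    pos <- sample(min(tx$exons$start):max(tx$exons$end), 1L)
    refb <- substr(chromseq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    v <- data.frame(chrom = g$chrom, pos = pos, ref = refb, alt = alt,
                    vclass = "SNV", key = variant_key(g$chrom, pos, refb, alt))
    got <- classify_snv(v, tx, g, genome$reference)$category
    want <- oracle_snv_category(pos, alt, tx, g$strand, chromseq)
    expect_identical(got, want, info = v$key)
  }
})

test_that("indel classification distinguishes frameshift and inframe", {
  hp <- hand_gene_plus()
  tx <- hp$gene$transcripts[[1L]]
  del2 <- data.frame(chrom = "chrT", pos = 31L, ref = "CAA", alt = "C",
                     vclass = "deletion", key = "chrT:31:CAA:C")
  expect_equal(classify_indel(del2, tx, hp$gene, hp$reference)$category,
               "frameshift")
  del3 <- data.frame(chrom = "chrT", pos = 31L, ref = "CAAG", alt = "C",
                     vclass = "deletion", key = "chrT:31:CAAG:C")
  expect_equal(classify_indel(del3, tx, hp$gene, hp$reference)$category,
               "inframe_indel")
  # deletion spanning only intronic essential bases
  dspl <- data.frame(chrom = "chrT", pos = 16L, ref = "AT", alt = "A",
                     vclass = "deletion", key = "chrT:16:AT:A")
  expect_equal(classify_indel(dspl, tx, hp$gene, hp$reference)$category,
               "splice_essential")
})

test_that("conservative LOF enforces non-terminal and all-isoform rules", {
  sim <- shared_sim()
  truth <- sim$planted$truth
  ann <- annotate_variants(sim$planted$variants, sim$genome$models,
                           sim$genome$reference,
                           predictors = sim$planted$predictors)
  j <- match(truth$key, ann$key)
  expect_false(any(is.na(j)))
  expect_identical(ann$conservative_lof[j], truth$expect_lof)
  expect_identical(ann$lof_class[j], truth$expect_lof_class)
  expect_identical(ann$dns[j], truth$expect_dns)
  # terminal-exon stopgains are classified stopgain but are not LOF
  term <- truth$class == "stopgain_terminal"
  expect_true(all(ann$category[j][term] == "stopgain"))
  expect_false(any(ann$conservative_lof[j][term]))
  # no variant is both LOF and DNS
  expect_false(any(ann$conservative_lof & ann$dns))
})

test_that("removing an isoform never turns a conservative LOF call false", {
  sim <- shared_sim()
  genome <- sim$genome
  truth <- sim$planted$truth
  lof_true <- truth[truth$expect_lof, ]
  for (i in seq_len(nrow(lof_true))) {
    g <- genome$models[[lof_true$gene_id[i]]]
    if (length(g$transcripts) < 2L) next
    v <- sim$planted$variants[
      sim$planted$variants$key == lof_true$key[i], ]
    # drop each transcript in turn; the all-isoform rules can only relax
    for (drop in seq_along(g$transcripts)) {
      g2 <- g
      g2$transcripts <- g$transcripts[-drop]
      per_tx <- lapply(g2$transcripts, function(tx) {
        if (v$vclass == "SNV") classify_snv(v, tx, g2, genome$reference)
        else classify_indel(v, tx, g2, genome$reference)
      })
      lof2 <- conservative_lof(v, g2, per_tx, genome$reference)
      expect_true(lof2$conservative_lof,
                  info = paste(lof_true$key[i], "minus tx", drop))
    }
  }
})

test_that("DNS consensus equals the popcount oracle over all 64 profiles", {
  preds <- c("SIFT", "PolyPhen2_HDIV", "LRT", "MutationTaster",
             "MutationAssessor", "FATHMM")
  for (mask in 0:63) {
    bits <- as.integer(intToBits(mask))[1:6]
    calls <- setNames(ifelse(bits == 1L, "damaging", "tolerated"), preds)
    expect_identical(dns_consensus(calls), sum(bits) >= 3L, info = mask)
  }
  # missing counts as not damaging
  calls <- setNames(c("damaging", "damaging", rep("missing", 4L)), preds)
  expect_false(dns_consensus(calls))
  # monotone: flipping tolerated -> damaging never loses a TRUE verdict
  set.seed(5)
  for (r in 1:50) {
    calls <- setNames(sample(c("damaging", "tolerated", "missing"), 6L,
                             replace = TRUE), preds)
    base <- dns_consensus(calls)
    k <- sample(6L, 1L)
    calls2 <- calls; calls2[k] <- "damaging"
    expect_true(!base || dns_consensus(calls2))
  }
  # threshold is configurable
  calls <- setNames(rep(c("damaging", "tolerated"), c(2L, 4L)), preds)
  expect_false(dns_consensus(calls))
  expect_true(dns_consensus(calls, min_damaging = 2L))
  expect_error(dns_consensus(calls[1:5]), "six predictors")
})
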