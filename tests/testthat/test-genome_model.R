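test_that("GTF round trip preserves a single-gene model", {
  hp <- hand_gene_plus()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(structure(list(hp = hp$gene), class = "GeneModelSet"), path)
  models <- load_gene_models(path)
  expect_length(models, 1L)
  g <- models[[1L]]
  expect_equal(g$gene_id, "hp")
  expect_length(g$transcripts, 1L)
  expect_equal(g$transcripts[[1L]]$exons, hp$gene$transcripts[[1L]]$exons)
  expect_equal(g$transcripts[[1L]]$cds, hp$gene$transcripts[[1L]]$cds)
})

test_that("transcripts with CDS length not divisible by 3 are rejected", {
  ex <- data.frame(start = 1L, end = 100L)
  expect_error(new_transcript("bad", ex, ex), "not a multiple of 3")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tx\texon\t1\t100\t.\t+\t.",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("chr1\tx\tCDS\t1\t100\t.\t+\t0",
          'gene_id "g"; transcript_id "t";', sep = "\t")), gtf)
  expect_error(load_gene_models(gtf), "t.*not a multiple of 3|multiple of 3")
})

test_that("CDS escaping its exon is a model error naming the transcript", {
  ex <- data.frame(start = 11L, end = 19L)
  cds <- data.frame(start = 11L, end = 22L)
  expect_error(new_transcript("esc", ex, cds), "esc")
})

test_that("coding_sequence splices plus-strand CDS in genomic order", {
  hp <- hand_gene_plus()
  expect_equal(coding_sequence(hp$gene$transcripts[[1L]], hp$reference,
                               "chrT", "+"),
               "ATGCGACAAGGGTGCTAA")
})

test_that("minus-strand coding_sequence is the reverse complement", {
  hm <- hand_gene_minus()
  expect_equal(coding_sequence(hm$gene$transcripts[[1L]], hm$reference,
                               "chrT", "-"),
               "ATGCGACAAGGGTGCTAA")
})

test_that("coding_sequence errors when CDS exceeds the reference", {
  hp <- hand_gene_plus()
  expect_error(coding_sequence(hp$gene$transcripts[[1L]],
                               c(chrT = "ACGT"), "chrT", "+"),
               "outside the reference|outside reference")
})

test_that("essential splice positions follow the +-2 intronic rule", {
  ex <- data.frame(start = c(1L, 201L), end = c(100L, 212L))
  tx <- new_transcript("s.t1", ex, ex[0, ])
  g <- new_gene_model("s", "S", "chr1", "+", list(tx))
  expect_equal(essential_splice_positions(g)$per_transcript$s.t1,
               c(101L, 102L, 199L, 200L))
})

test_that("single-exon transcripts have no essential splice positions", {
  ns <- hand_gene_no_stopgain(1L)
  ess <- essential_splice_positions(ns$gene)
  expect_length(ess$per_transcript[[1L]], 0L)
  expect_length(ess$all_isoform, 0L)
})

test_that("all-isoform splice set is the intersection across isoforms", {
  ti <- hand_gene_two_isoform()
  ess <- essential_splice_positions(ti$gene)
  # full isoform: introns 17..30 and 37..50; skip isoform: merged 17..50
  expect_setequal(ess$per_transcript$ti.t1,
                  c(17L, 18L, 29L, 30L, 37L, 38L, 49L, 50L))
  expect_setequal(ess$per_transcript$ti.t2, c(17L, 18L, 49L, 50L))
  expect_setequal(ess$all_isoform, c(17L, 18L, 49L, 50L))
})

test_that("exonic positions are the union over transcripts", {
  ex1 <- data.frame(start = 1L, end = 100L)
  ex2 <- data.frame(start = 51L, end = 150L)
  g <- new_gene_model("u", "U", "chr1", "+", list(
    new_transcript("u.t1", ex1, ex1[0, ]),
    new_transcript("u.t2", ex2, ex2[0, ])))
  expect_length(exonic_positions(g), 150L)
  g1 <- new_gene_model("u1", "U1", "chr1", "+", list(
    new_transcript("a", ex1, ex1[0, ]), new_transcript("b", ex1, ex1[0, ])))
  expect_length(exonic_positions(g1), 100L)
})

test_that("synthetic genomes satisfy the gene-model invariants", {
  sim <- shared_sim()
  models <- sim$genome$models
  expect_length(models, 50L)
  for (g in models) {
    for (tx in g$transcripts) {
      cds_len <- sum(tx$cds$end - tx$cds$start + 1L)
      expect_identical(cds_len %% 3L, 0L)
      # generator-recorded ground-truth CDS string
      got <- coding_sequence(tx, sim$genome$reference, g$chrom, g$strand)
      expect_identical(got, unname(
        sim$genome$meta[[g$gene_id]]$cds_truth[[tx$transcript_id]]))
      # no internal stop in any isoform
      aa <- translate_cds(got)
      expect_false(grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
      # 4 essential positions per intron
      ess <- essential_splice_positions(g)$per_transcript[[tx$transcript_id]]
      expect_length(ess, 4L * (nrow(tx$exons) - 1L))
      # exonic union contains every CDS position
      cds_pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
        tx$cds$start[i]:tx$cds$end[i]))
      expect_true(all(cds_pos %in% exonic_positions(g)))
    }
  }
})

test_that("written synthetic genomes reload identically", {
  sim <- shared_sim()
  dir <- withr::local_tempdir()
  paths <- write_genome(sim$genome, dir)
  models <- load_gene_models(paths[["gtf"]])
  expect_setequal(names(models), names(sim$genome$models))
  for (gid in names(models)) {
    a <- models[[gid]]; b <- sim$genome$models[[gid]]
    expect_equal(length(a$transcripts), length(b$transcripts))
    for (tid in names(b$transcripts))
      expect_equal(a$transcripts[[tid]]$exons, b$transcripts[[tid]]$exons)
  }
  ref <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(ref[["chr1"]]),
               unname(sim$genome$reference[["chr1"]]))
})
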