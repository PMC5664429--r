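# Seeded synthetic-data generators: a toy genome with multi-isoform
# genes, planted variants of every consequence class with a
# machine-readable truth table, simulated trios realizing each
# inheritance mode, and the worked-example fixture encoding the
# discovery-cohort tables. Everything is deterministic under the seed.
#
# Simulator simplification (documented in the vignette): exon CDS lengths
# are multiples of 3 (phase-0 introns), so isoforms that skip an internal
# exon keep frame and share the remaining codons; open reading frames are
# stop-free in every isoform by construction.

NONSTOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                  DNA_BASES, paste0)), STOP_CODONS)

#' Simulation specification
#'
#' Defaults emulate the study's shapes at desk scale: a 342-case cohort,
#' an internal comparison panel of 10,984 alleles (5492 individuals), and
#' a 50-gene toy genome small enough for exhaustive brute-force checks.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_genes Number of genes.
#' @param transcripts_per_gene,exons_per_transcript,codons_per_exon,
#'   intron_length Integer ranges `c(min, max)`.
#' @param intergenic Bases between genes.
#' @param n_cases Case-cohort size.
#' @param n_comparison_samples Per-sample comparison subset used for
#'   observed-LOF counting (panel allele totals are set independently).
#' @param internal_total_alleles Allele total of the internal panel.
#' @param public_panels Named integer vector of public-panel allele totals.
#' @param planted data.frame (class, tier, count) of variants to plant;
#'   see [default_planted_spec()].
#' @param x_fraction Fraction of genes placed on chromosome X.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, n_genes = 50L,
                     transcripts_per_gene = c(1L, 3L),
                     exons_per_transcript = c(2L, 6L),
                     codons_per_exon = c(4L, 8L),
                     intron_length = c(30L, 80L), intergenic = 150L,
                     n_cases = 342L, n_comparison_samples = 60L,
                     internal_total_alleles = 10984L,
                     public_panels = c(KG1000 = 5008L, ESP = 13006L,
                                       ExAC = 121412L),
                     planted = default_planted_spec(),
                     x_fraction = 0.1) {
  stopifnot(seed == as.integer(seed), n_genes >= 1L,
            exons_per_transcript[1L] >= 2L, all(planted$count >= 0L))
  structure(as.list(environment()), class = "sim_spec")
}

#' Default planted-variant specification
#'
#' One row per (consequence class, rarity tier) with the planted count.
#' Negative controls (terminal-exon stopgain, partial-isoform splice and
#' frameshift, inframe indels, 2-of-6 missense, recurrent LOF,
#' non-candidate-gene LOF) are first-class plantings.
#'
#' @return data.frame (class, tier, count).
#' @export
default_planted_spec <- function() {
  data.frame(
    class = c("stopgain_nonterminal", "stopgain_terminal", "splice_all",
              "splice_partial", "frameshift_all", "frameshift_partial",
              "inframe", "missense_dns", "missense_nondns", "synonymous",
              "recurrent_lof", "stopgain_nonapriori"),
    tier = c("case_exclusive", "case_exclusive", "case_exclusive",
             "case_exclusive", "case_exclusive", "case_exclusive",
             "case_exclusive", "rare", "rare", "rare",
             "case_exclusive", "case_exclusive"),
    count = c(5L, 3L, 4L, 3L, 4L, 3L, 2L, 5L, 3L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Simulate a toy genome
#'
#' Generates multi-isoform genes with stop-free open reading frames.
#' Multi-transcript genes include an isoform that skips an internal
#' exon, so that shared and private introns/exons exercise the
#' all-isoform LOF rules.
#'
#' @param spec A [sim_spec()].
#' @return List of class `sim_genome`: `models` (`GeneModelSet`),
#'   `reference` (named character by chromosome), `meta` (per-gene
#'   generation record incl. ground-truth CDS strings per transcript).
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  n_x <- max(0L, round(spec$n_genes * spec$x_fraction))
  chroms <- c(rep(c("chr1", "chr2", "chr3", "chr4"),
                  length.out = spec$n_genes - n_x),
              rep("chrX", n_x))
  cursors <- list()
  seqs <- list()
  meta <- list()
  models <- list()
  for (g in seq_len(spec$n_genes)) {
    chrom <- chroms[g]
    if (is.null(cursors[[chrom]])) { cursors[[chrom]] <- 0L
                                     seqs[[chrom]] <- character(0) }
    n_ex <- sample(spec$exons_per_transcript[1L]:spec$exons_per_transcript[2L],
                   1L)
    cc <- sample(spec$codons_per_exon[1L]:spec$codons_per_exon[2L], n_ex,
                 replace = TRUE)
    n_codons <- sum(cc)
    codons <- c("ATG", sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    # codons of transcription-order exon j
    exon_codons <- split(codons, rep(seq_len(n_ex), cc))
    strand <- sample(c("+", "-"), 1L)
    n_tx <- sample(spec$transcripts_per_gene[1L]:spec$transcripts_per_gene[2L],
                   1L)
    skip_candidates <- if (n_ex >= 3L) 2:(n_ex - 1L) else integer(0)
    if (!length(skip_candidates)) n_tx <- 1L
    n_tx <- min(n_tx, 1L + length(skip_candidates))
    skips <- if (n_tx > 1L) sample(skip_candidates,
                                   n_tx - 1L) else integer(0)

    # genomic layout: intergenic gap, then exons (ascending) with introns
    pieces <- character(0)
    cur <- cursors[[chrom]]
    pieces <- c(pieces, random_dna(spec$intergenic))
    cur <- cur + spec$intergenic
    exon_iv <- data.frame(start = integer(n_ex), end = integer(n_ex))
    genomic_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    for (i in seq_len(n_ex)) {
      if (i > 1L) {
        il <- sample(spec$intron_length[1L]:spec$intron_length[2L], 1L)
        pieces <- c(pieces, random_dna(il))
        cur <- cur + il
      }
      tx_exon <- genomic_order[i]   # transcription index of this exon
      content <- paste(exon_codons[[tx_exon]], collapse = "")
      if (strand == "-") content <- revcomp(content)
      exon_iv$start[i] <- cur + 1L
      exon_iv$end[i] <- cur + nchar(content)
      pieces <- c(pieces, content)
      cur <- cur + nchar(content)
    }
    seqs[[chrom]] <- c(seqs[[chrom]], pieces)
    cursors[[chrom]] <- cur

    gene_id <- sprintf("G%04d", g)
    txs <- list()
    tx_exons <- list(full = seq_len(n_ex))
    txs[[1L]] <- new_transcript(paste0(gene_id, ".t1"), exon_iv, exon_iv)
    if (length(skips)) for (s in seq_along(skips)) {
      keep_tx_idx <- setdiff(seq_len(n_ex), skips[s])
      keep_genomic <- which(genomic_order %in% keep_tx_idx)
      iv <- exon_iv[keep_genomic, , drop = FALSE]
      txs[[s + 1L]] <- new_transcript(sprintf("%s.t%d", gene_id, s + 1L),
                                      iv, iv)
      tx_exons[[s + 1L]] <- keep_tx_idx
    }
    gm <- new_gene_model(gene_id, sprintf("SYN%04d", g), chrom, strand, txs)
    models[[gene_id]] <- gm
    cds_truth <- c(paste(codons, collapse = ""),
                   vapply(skips, function(sk)
                     paste(unlist(exon_codons[setdiff(seq_len(n_ex), sk)]),
                           collapse = ""), character(1)))
    names(cds_truth) <- vapply(txs, `[[`, "", "transcript_id")
    meta[[gene_id]] <- list(gene_id = gene_id, symbol = gm$symbol,
                            chrom = chrom, strand = strand,
                            n_exons = n_ex, codons = codons,
                            exon_codon_counts = cc, skips = skips,
                            exon_iv = exon_iv, genomic_order = genomic_order,
                            cds_truth = cds_truth)
  }
  reference <- vapply(seqs, paste, character(1), collapse = "")
  # pad chromosomes to a common comfortable tail
  reference <- vapply(reference, function(s)
    paste0(s, strrep("A", 50L)), character(1))
  structure(list(models = structure(models, class = "GeneModelSet"),
                 reference = reference, meta = meta, spec = spec),
            class = "sim_genome")
}

# ---- placement helpers -----------------------------------------------------

# map a CDS index of the full transcript to genomic position
full_tx_cds_pos <- function(gene) {
  tx <- gene$transcripts[[1L]]
  pos <- interval_positions(tx$cds)
  if (attr_strand(gene) == "-") rev(pos) else pos
}

attr_strand <- function(gene) gene$strand

# transcription exon index containing codon `cn` given per-exon codon counts
codon_exon <- function(cn, cc) findInterval(cn - 1L, cumsum(c(0L, cc)),
                                            rightmost.closed = FALSE)

# Find a single-base substitution creating (or not) a stop, in the given
# transcription-order exons. Returns genomic pos/ref/alt or NULL.
find_snv_site <- function(genome, gene_id, target, exons_allowed, used) {
  m <- genome$meta[[gene_id]]
  gene <- genome$models[[gene_id]]
  cds_pos <- full_tx_cds_pos(gene)   # genomic position of CDS index i
  n_codons <- length(m$codons)
  for (cn in seq(2L, n_codons - 1L)) {
    ex <- codon_exon(cn, m$exon_codon_counts)
    if (!ex %in% exons_allowed) next
    old <- m$codons[cn]
    for (b in 1:3) {
      idx <- (cn - 1L) * 3L + b
      gpos <- cds_pos[idx]
      if (gpos %in% used) next
      for (alt_tx in setdiff(DNA_BASES, substr(old, b, b))) {
        new <- old; substr(new, b, b) <- alt_tx
        ok <- switch(target,
          stopgain = new %in% STOP_CODONS,
          missense = !(new %in% STOP_CODONS) && aa_one(new) != aa_one(old),
          synonymous = !(new %in% STOP_CODONS) && aa_one(new) == aa_one(old))
        if (!ok) next
        if (m$strand == "+") {
          return(list(pos = gpos, ref = substr(old, b, b), alt = alt_tx,
                      codon = cn))
        } else {
          return(list(pos = gpos, ref = comp_base(substr(old, b, b)),
                      alt = comp_base(alt_tx), codon = cn))
        }
      }
    }
  }
  NULL
}

# exons (transcription order) shared by all transcripts of the gene
shared_exons <- function(meta) setdiff(seq_len(meta$n_exons), meta$skips)

# genomic interval of transcription-order exon j
exon_interval <- function(meta, j) {
  i <- which(meta$genomic_order == j)
  c(meta$exon_iv$start[i], meta$exon_iv$end[i])
}

plant_state <- function(genome) {
  new.env(parent = emptyenv())
}

used_positions <- function(state, gene_id) {
  get0(gene_id, envir = state, ifnotfound = integer(0))
}

mark_used <- function(state, gene_id, pos) {
  assign(gene_id, c(used_positions(state, gene_id), pos), envir = state)
}

# find a planting site for one requested class; NULL when gene unsuitable
place_variant <- function(genome, gene_id, class, state) {
  m <- genome$meta[[gene_id]]
  gene <- genome$models[[gene_id]]
  ref_chr <- genome$reference[[m$chrom]]
  used <- used_positions(state, gene_id)
  grab <- function(pos, len) substr(ref_chr, pos, pos + len - 1L)
  ess <- essential_splice_positions(gene)
  site <- NULL
  terminal <- m$n_exons
  nonterminal_shared <- setdiff(shared_exons(m), terminal)
  if (class %in% c("stopgain_nonterminal", "recurrent_lof",
                   "stopgain_nonapriori")) {
    if (!length(nonterminal_shared)) return(NULL)
    s <- find_snv_site(genome, gene_id, "stopgain", nonterminal_shared, used)
    if (is.null(s)) return(NULL)
    site <- data.frame(pos = s$pos, ref = s$ref, alt = s$alt)
  } else if (class == "stopgain_terminal") {
    s <- find_snv_site(genome, gene_id, "stopgain", terminal, used)
    if (is.null(s)) return(NULL)
    site <- data.frame(pos = s$pos, ref = s$ref, alt = s$alt)
  } else if (class %in% c("missense_dns", "missense_nondns")) {
    s <- find_snv_site(genome, gene_id, "missense", shared_exons(m), used)
    if (is.null(s)) return(NULL)
    site <- data.frame(pos = s$pos, ref = s$ref, alt = s$alt)
  } else if (class == "synonymous") {
    s <- find_snv_site(genome, gene_id, "synonymous", shared_exons(m), used)
    if (is.null(s)) return(NULL)
    site <- data.frame(pos = s$pos, ref = s$ref, alt = s$alt)
  } else if (class == "splice_all") {
    cand <- setdiff(ess$all_isoform, used)
    if (!length(cand)) return(NULL)
    p <- cand[1L]
    refb <- grab(p, 1L)
    site <- data.frame(pos = p, ref = refb,
                       alt = sample(setdiff(DNA_BASES, refb), 1L))
  } else if (class == "splice_partial") {
    partial <- setdiff(unique(unlist(ess$per_transcript)), ess$all_isoform)
    cand <- setdiff(partial, used)
    if (!length(cand)) return(NULL)
    p <- cand[1L]
    refb <- grab(p, 1L)
    site <- data.frame(pos = p, ref = refb,
                       alt = sample(setdiff(DNA_BASES, refb), 1L))
  } else if (class %in% c("frameshift_all", "inframe")) {
    sh <- shared_exons(m)
    if (!length(sh)) return(NULL)
    for (j in sh) {
      iv <- exon_interval(m, j)
      a <- iv[1L] + 3L
      dlen <- if (class == "inframe") 3L else 1L
      if (a + dlen > iv[2L] || any((a:(a + dlen)) %in% used)) next
      site <- data.frame(pos = a, ref = grab(a, dlen + 1L), alt = grab(a, 1L))
      break
    }
    if (is.null(site)) return(NULL)
  } else if (class == "frameshift_partial") {
    if (!length(m$skips)) return(NULL)
    j <- m$skips[1L]
    iv <- exon_interval(m, j)
    a <- iv[1L] + 4L
    if (a + 1L > iv[2L] || any((a:(a + 1L)) %in% used)) return(NULL)
    site <- data.frame(pos = a, ref = grab(a, 2L), alt = grab(a, 1L))
  } else stop("unknown planted class ", class)
  mark_used(state, gene_id, site$pos:(site$pos + nchar(site$ref) - 1L))
  site
}

planted_truth_row <- function(class) {
  switch(class,
    stopgain_nonterminal = ,
    recurrent_lof = ,
    stopgain_nonapriori = list(lof = TRUE, lof_class = "stopgain_lof",
                               dns = FALSE),
    splice_all = list(lof = TRUE, lof_class = "splice_lof", dns = FALSE),
    frameshift_all = list(lof = TRUE, lof_class = "frameshift_lof",
                          dns = FALSE),
    missense_dns = list(lof = FALSE, lof_class = "none", dns = TRUE),
    list(lof = FALSE, lof_class = "none", dns = FALSE))
}

#' Plant variants in a simulated genome
#'
#' Plants the classes requested by the spec (with negative controls),
#' assigns each a rarity tier via frequency-panel records, carrier cases,
#' predictor profiles for missense variants, and a comparison-cohort
#' genotype subset with known per-gene LOF allele counts.
#'
#' @param spec A [sim_spec()].
#' @param genome From [simulate_genome()].
#' @return List of class `sim_variants`: `variants`, `genotypes` (cases),
#'   `quality`, `panels`, `predictors`, `apriori`, `truth`,
#'   `comparison` (list: variants, genotypes, truth_obs per gene).
#' @export
plant_variants <- function(spec, genome) {
  set.seed(spec$seed + 1L)
  state <- plant_state(genome)
  gene_ids <- names(genome$models)
  # genes with a skipping isoform, needed by partial-isoform controls
  multi <- gene_ids[vapply(genome$meta, function(m) length(m$skips) > 0L,
                           logical(1))]
  nonapriori_genes <- tail(gene_ids, 2L)
  rows <- list(); truth <- list()
  gt <- list()
  case_ids <- sprintf("CASE%04d", seq_len(spec$n_cases))
  panel_rows <- list(); pred_rows <- list()
  gi <- 0L
  pick_gene <- function(class) {
    pool <- if (class %in% c("splice_partial", "frameshift_partial")) multi
      else if (class == "stopgain_nonapriori") nonapriori_genes
      else setdiff(gene_ids, nonapriori_genes)
    for (k in seq_along(pool)) {
      gi <<- gi + 1L
      g <- pool[(gi - 1L) %% length(pool) + 1L]
      s <- place_variant(genome, g, class, state)
      if (!is.null(s)) return(list(gene = g, site = s))
    }
    NULL
  }
  for (r in seq_len(nrow(spec$planted))) {
    class <- spec$planted$class[r]; tier <- spec$planted$tier[r]
    for (cnt in seq_len(spec$planted$count[r])) {
      hit <- pick_gene(class)
      if (is.null(hit))
        stop("cannot place planted class ", class,
             ": no suitable gene remains")
      m <- genome$meta[[hit$gene]]
      key <- variant_key(m$chrom, hit$site$pos, hit$site$ref, hit$site$alt)
      n_carriers <- if (class == "recurrent_lof") 3L else 1L
      carriers <- sample(case_ids, n_carriers)
      exp <- planted_truth_row(class)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = m$chrom, pos = hit$site$pos, ref = hit$site$ref,
        alt = hit$site$alt, key = key)
      gt[[key]] <- carriers
      # frequency-panel records realizing the tier
      internal_ac <- switch(tier, case_exclusive = NA_integer_, rare = 2L,
                            common = 100L)
      if (!is.na(internal_ac))
        panel_rows[[length(panel_rows) + 1L]] <- data.frame(
          chrom = m$chrom, pos = hit$site$pos, ref = hit$site$ref,
          alt = hit$site$alt, panel = "internal", alt_count = internal_ac,
          total_alleles = spec$internal_total_alleles)
      for (p in names(spec$public_panels))
        panel_rows[[length(panel_rows) + 1L]] <- data.frame(
          chrom = m$chrom, pos = hit$site$pos, ref = hit$site$ref,
          alt = hit$site$alt, panel = p,
          alt_count = if (tier == "common") NA_integer_ else
            sample(0:2, 1L),
          total_alleles = spec$public_panels[[p]])
      if (grepl("^missense", class)) {
        n_dam <- if (class == "missense_dns") sample(3:6, 1L) else
          sample(0:2, 1L)
        calls <- c(rep("D", n_dam), rep("T", 6L - n_dam))[sample.int(6L)]
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          chrom = m$chrom, pos = hit$site$pos, ref = hit$site$ref,
          alt = hit$site$alt,
          SIFT = calls[1], PolyPhen2_HDIV = calls[2], LRT = calls[3],
          MutationTaster = calls[4], MutationAssessor = calls[5],
          FATHMM = calls[6],
          cadd_scaled = round(runif(1, 10, 40), 2))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        key = key, gene_id = m$gene_id, symbol = m$symbol, class = class,
        expect_lof = exp$lof, expect_lof_class = exp$lof_class,
        expect_dns = exp$dns, tier = tier, n_carriers = n_carriers,
        carriers = paste(carriers, collapse = ","),
        apriori = !(m$gene_id %in% nonapriori_genes),
        funnel_expected = exp$lof && tier == "case_exclusive" &&
          n_carriers <= 2L && !(m$gene_id %in% nonapriori_genes))
    }
  }
  variants <- do.call(rbind, rows)
  variants$vclass <- classify_vclass(variants$ref, variants$alt)
  truth <- do.call(rbind, truth)
  genotypes <- matrix(0L, nrow(variants), spec$n_cases,
                      dimnames = list(variants$key, case_ids))
  for (k in names(gt)) genotypes[k, gt[[k]]] <- 1L
  quality <- data.frame(posterior_prob = 0.99, depth = 50L,
                        variant_reads = 25L, allelic_fraction = 0.5,
                        max_strand_fraction = 0.55, is_homref_call = FALSE,
                        row.names = NULL)[rep(1L, nrow(variants)), ]
  rownames(quality) <- NULL
  panels <- do.call(rbind, panel_rows)
  # "common" public records get a frequency clearly above the ceiling
  high <- is.na(panels$alt_count)
  panels$alt_count[high] <-
    as.integer(round(0.01 * panels$total_alleles[high]))
  panels$key <- variant_key(panels$chrom, panels$pos, panels$ref, panels$alt)
  predictors <- if (length(pred_rows)) {
    pr <- do.call(rbind, pred_rows)
    pr$key <- variant_key(pr$chrom, pr$pos, pr$ref, pr$alt)
    pr
  } else NULL
  apriori <- data.frame(
    gene = vapply(genome$meta[setdiff(gene_ids, nonapriori_genes)],
                  `[[`, "", "symbol"),
    sources = vapply(seq_len(length(gene_ids) - 2L), function(i)
      paste(sample(APRIORI_SOURCES, sample(1:3, 1L)), collapse = ","),
      character(1)), row.names = NULL)

  comparison <- plant_comparison_cohort(spec, genome, state)
  structure(list(variants = variants, genotypes = genotypes,
                 quality = quality, panels = panels, predictors = predictors,
                 apriori = apriori, truth = truth, comparison = comparison),
            class = "sim_variants")
}

# comparison-cohort LOF sites with known per-gene allele counts
plant_comparison_cohort <- function(spec, genome, state) {
  gene_ids <- head(names(genome$models), 10L)
  samples <- sprintf("CMP%04d", seq_len(spec$n_comparison_samples))
  rows <- list(); alleles <- list()
  truth_obs <- setNames(integer(length(gene_ids)), gene_ids)
  for (g in gene_ids) {
    n_sites <- sample(0:2, 1L)
    if (!n_sites) next
    for (s in seq_len(n_sites)) {
      m <- genome$meta[[g]]
      site <- place_variant(genome, g, "stopgain_nonterminal", state)
      if (is.null(site)) next
      key <- variant_key(m$chrom, site$pos, site$ref, site$alt)
      carriers <- sample(samples, sample(1:4, 1L))
      hom <- rbinom(length(carriers), 1L, 0.2)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = m$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
        key = key)
      alleles[[key]] <- setNames(1L + hom, carriers)
      truth_obs[g] <- truth_obs[g] + sum(1L + hom)
    }
  }
  if (!length(rows))
    return(list(variants = NULL, genotypes = NULL, truth_obs = truth_obs))
  variants <- do.call(rbind, rows)
  variants$vclass <- classify_vclass(variants$ref, variants$alt)
  genotypes <- matrix(0L, nrow(variants), length(samples),
                      dimnames = list(variants$key, samples))
  for (k in names(alleles)) genotypes[k, names(alleles[[k]])] <- alleles[[k]]
  list(variants = variants, genotypes = genotypes, truth_obs = truth_obs)
}

#' Simulate trios with planted inheritance modes
#'
#' Creates one trio per requested mode instance, assigns each a distinct
#' exonic SNV, and realizes the mode through parental genotypes
#' (Mendelian-consistent by construction). Compound-het requests plant a
#' trans pair in one gene; `cis_control` plants a same-parent pair whose
#' truth mode is `inherited_dominant` (no compound het).
#'
#' @param spec A [sim_spec()].
#' @param genome From [simulate_genome()].
#' @param modes Named integer vector over
#'   `{de_novo, inherited_dominant, recessive_homozygous,
#'   recessive_compound_het, cis_control, x_linked, unknown, unresolved}`.
#' @return List of class `sim_trios`: `variants`, `genotypes`
#'   (variants x samples incl. parents), `hemi` (logical matrix), `ped`,
#'   `truth` (variant/trio/mode rows).
#' @export
simulate_trios <- function(spec, genome,
                           modes = c(de_novo = 9L, inherited_dominant = 13L,
                                     recessive_homozygous = 2L,
                                     recessive_compound_het = 2L,
                                     cis_control = 1L, x_linked = 2L,
                                     unknown = 3L, unresolved = 1L)) {
  set.seed(spec$seed + 2L)
  state <- plant_state(genome)
  gene_ids <- names(genome$models)
  x_genes <- gene_ids[vapply(genome$meta, function(m) m$chrom == "chrX",
                             logical(1))]
  auto_genes <- setdiff(gene_ids, x_genes)
  if (any(modes["x_linked"] > 0L) && !length(x_genes))
    stop("x_linked mode requested but no gene lies on chromosome X")
  n_trios <- sum(modes)
  trio_modes <- rep(names(modes), modes)
  probands <- sprintf("P%04d", seq_len(n_trios))
  mothers <- paste0(probands, "_M"); fathers <- paste0(probands, "_F")
  samples <- c(probands, mothers, fathers)
  rows <- list(); truth <- list(); gts <- list(); hemis <- list()
  ped <- list()
  gcycle <- 0L
  next_site <- function(pool) {
    for (k in seq_along(pool)) {
      gcycle <<- gcycle + 1L
      g <- pool[(gcycle - 1L) %% length(pool) + 1L]
      s <- place_variant(genome, g, "missense_dns", state)
      if (is.null(s)) s <- place_variant(genome, g, "synonymous", state)
      if (!is.null(s)) return(list(gene = g, site = s))
    }
    stop("ran out of plantable trio sites; enlarge the genome")
  }
  add_variant <- function(gene, site, gt3, hemi3 = c(FALSE, FALSE, FALSE)) {
    m <- genome$meta[[gene]]
    key <- variant_key(m$chrom, site$pos, site$ref, site$alt)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = m$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      key = key)
    gts[[key]] <<- gt3; hemis[[key]] <<- hemi3
    key
  }
  for (i in seq_len(n_trios)) {
    mode <- trio_modes[i]
    sex <- if (mode == "x_linked") "male" else sample(c("male", "female"), 1L)
    m_avail <- !(mode == "unresolved")
    f_avail <- !(mode %in% c("unknown", "unresolved"))
    pool <- if (mode == "x_linked") x_genes else auto_genes
    hit <- next_site(pool)
    gt3 <- switch(mode,
      de_novo = c(1L, 0L, 0L),
      inherited_dominant = {
        from_mother <- sample(c(TRUE, FALSE), 1L)
        c(1L, if (from_mother) 1L else 0L, if (from_mother) 0L else 1L)
      },
      recessive_homozygous = c(2L, 1L, 1L),
      x_linked = c(1L, 1L, 0L),
      unknown = c(1L, 0L, 0L),
      unresolved = c(1L, 0L, 0L),
      recessive_compound_het = c(1L, 1L, 0L),
      cis_control = c(1L, 1L, 0L))
    hemi3 <- if (mode == "x_linked") c(TRUE, FALSE, TRUE) else rep(FALSE, 3L)
    key <- add_variant(hit$gene, hit$site, gt3, hemi3)
    partner <- NA_character_
    if (mode %in% c("recessive_compound_het", "cis_control")) {
      s2 <- place_variant(genome, hit$gene, "synonymous", state)
      if (is.null(s2)) s2 <- place_variant(genome, hit$gene, "missense_dns",
                                           state)
      if (is.null(s2)) stop("no second site available in ", hit$gene)
      gt2 <- if (mode == "recessive_compound_het") c(1L, 0L, 1L)
             else c(1L, 1L, 0L)
      partner <- add_variant(hit$gene, s2, gt2)
      truth[[length(truth) + 1L]] <- data.frame(
        key = partner, trio = probands[i], gene_id = hit$gene,
        mode = if (mode == "recessive_compound_het")
          "recessive_compound_het" else "inherited_dominant",
        partner = if (mode == "recessive_compound_het") key else
          NA_character_)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      key = key, trio = probands[i], gene_id = hit$gene,
      mode = switch(mode, recessive_compound_het = "recessive_compound_het",
                    cis_control = "inherited_dominant", mode),
      partner = partner)
    ped[[i]] <- data.frame(
      family_id = sprintf("F%04d", i), sample_id = probands[i],
      father_id = if (f_avail) fathers[i] else "0",
      mother_id = if (m_avail) mothers[i] else "0",
      sex = if (sex == "male") 1L else 2L, phenotype = "2")
  }
  variants <- do.call(rbind, rows)
  variants$vclass <- classify_vclass(variants$ref, variants$alt)
  genotypes <- matrix(0L, nrow(variants), length(samples),
                      dimnames = list(variants$key, samples))
  hemi <- matrix(FALSE, nrow(variants), length(samples),
                 dimnames = dimnames(genotypes))
  for (i in seq_len(n_trios)) {
    mode <- trio_modes[i]
    keys <- vapply(truth, function(t) t$key, "")[
      vapply(truth, function(t) t$trio, "") == probands[i]]
    for (k in keys) {
      g3 <- gts[[k]]; h3 <- hemis[[k]]
      genotypes[k, probands[i]] <- g3[1L]
      genotypes[k, mothers[i]] <- g3[2L]
      genotypes[k, fathers[i]] <- g3[3L]
      hemi[k, c(probands[i], fathers[i])] <- h3[c(1L, 3L)]
    }
  }
  ped <- do.call(rbind, ped)
  avail_f <- ped$father_id[ped$father_id != "0"]
  avail_m <- ped$mother_id[ped$mother_id != "0"]
  ped <- rbind(ped,
               data.frame(family_id = sub("_F$", "", avail_f),
                          sample_id = avail_f, father_id = "0",
                          mother_id = "0", sex = 1L, phenotype = "1"),
               data.frame(family_id = sub("_M$", "", avail_m),
                          sample_id = avail_m, father_id = "0",
                          mother_id = "0", sex = 2L, phenotype = "1"))
  # parents' genotype columns only exist when the pedigree lists them; drop
  # unavailable parents' columns so availability matches the pedigree
  listed <- unique(c(ped$sample_id, avail_f, avail_m))
  genotypes <- genotypes[, colnames(genotypes) %in% listed, drop = FALSE]
  hemi <- hemi[, colnames(genotypes), drop = FALSE]
  truth <- do.call(rbind, truth)
  structure(list(variants = variants, genotypes = genotypes, hemi = hemi,
                 ped = ped, truth = truth), class = "sim_trios")
}

# ---- file emission ---------------------------------------------------------

#' Write a simulated genome to GTF + FASTA
#'
#' @param genome From [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "genes.gtf")
  fa <- file.path(dir, "genome.fa")
  write_gtf(genome$models, gtf)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome$reference)), fa)
  c(gtf = gtf, fasta = fa)
}

#' Write planted case data to VCF/TSV files
#'
#' @param sim From [plant_variants()].
#' @param dir Output directory.
#' @return Named character vector of written paths.
#' @export
write_case_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cases.vcf")
  write_vcf(sim$variants, sim$genotypes, sim$quality, vcf)
  panels <- file.path(dir, "panels.tsv")
  write.table(sim$panels[, c("chrom", "pos", "ref", "alt", "panel",
                             "alt_count", "total_alleles")],
              panels, sep = "\t", quote = FALSE, row.names = FALSE)
  apriori <- file.path(dir, "apriori_genes.tsv")
  write.table(sim$apriori, apriori, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(case_vcf = vcf, panels = panels, apriori = apriori, truth = truth)
  if (!is.null(sim$predictors)) {
    pred <- file.path(dir, "predictors.tsv")
    write.table(sim$predictors[, c("chrom", "pos", "ref", "alt",
                                   PREDICTOR_NAMES, "cadd_scaled")],
                pred, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, predictors = pred)
  }
  out
}

#' Write simulated trios to VCF + PED
#'
#' @param trios From [simulate_trios()].
#' @param dir Output directory.
#' @return Named character vector of written paths.
#' @export
write_trio_data <- function(trios, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "trios.vcf")
  q <- data.frame(posterior_prob = 0.99, depth = 50L, variant_reads = 25L,
                  allelic_fraction = 0.5, max_strand_fraction = 0.55,
                  is_homref_call = FALSE)[rep(1L, nrow(trios$variants)), ]
  write_vcf(trios$variants, trios$genotypes, q, vcf, hemi = trios$hemi)
  ped <- file.path(dir, "trios.ped")
  write.table(trios$ped, ped, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  c(trio_vcf = vcf, ped = ped)
}
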