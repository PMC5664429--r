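# Worked-example fixture: the discovery-cohort gene table (shipped as
# inst/extdata/discovery_genes.tsv) realized as a toy genome, a 342-case
# cohort VCF in which only the tabulated case IDs carry candidate LOF
# alleles, trio genotypes realizing each tabulated inheritance mode, the
# a-priori gene list, clinical-cohort carrier/phenotype flags, a planted
# known-pathogenic table, and the expected-report values for assertions.
#
# The shipped table lists 27 LOF rows with two duplicated case IDs, i.e.
# 25 unique carrier cases; the study's prose summary prints 26 carriers
# (7.6% of 342). The fixture reproduces the table rows literally and the
# expected-report records both the printed values and the values the
# table itself implies (see the methods vignette).

FIXTURE_SEED <- 424242L

mode_label_to_mode <- function(x) {
  c("De novo" = "de_novo", "Inherited" = "inherited_dominant",
    "Recessive" = "recessive_homozygous", "X-linked" = "x_linked",
    "Unknown" = "unknown")[x]
}

#' Read the shipped discovery-gene table
#'
#' @return data.frame (gene, chrom, case_id, mode, clinical counts,
#'   support tags, OP percentile and pLI reference columns).
#' @export
discovery_gene_table <- function() {
  read.table(system.file("extdata", "discovery_genes.tsv",
                         package = "lofprior"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

# deterministic single-transcript ORF gene on a chromosome cursor
fixture_gene <- function(gene_id, symbol, chrom, cursor, n_codons = 16L,
                         strand = "+") {
  cc <- c(5L, n_codons - 10L, 5L)
  codons <- c("ATG", sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  codons[3L] <- "CAA"   # guarantees a stop-reachable non-terminal codon
  exon_codons <- split(codons, rep(seq_along(cc), cc))
  pieces <- random_dna(80L)
  cur <- cursor + 80L
  exon_iv <- data.frame(start = integer(3L), end = integer(3L))
  genomic_order <- if (strand == "+") 1:3 else 3:1
  for (i in 1:3) {
    if (i > 1L) {
      pieces <- paste0(pieces, random_dna(40L))
      cur <- cur + 40L
    }
    content <- paste(exon_codons[[genomic_order[i]]], collapse = "")
    if (strand == "-") content <- revcomp(content)
    exon_iv$start[i] <- cur + 1L
    exon_iv$end[i] <- cur + nchar(content)
    pieces <- paste0(pieces, content)
    cur <- cur + nchar(content)
  }
  tx <- new_transcript(paste0(gene_id, ".t1"), exon_iv, exon_iv)
  model <- new_gene_model(gene_id, symbol, chrom, strand, list(tx))
  meta <- list(gene_id = gene_id, symbol = symbol, chrom = chrom,
               strand = strand, n_exons = 3L, codons = codons,
               exon_codon_counts = cc, skips = integer(0),
               exon_iv = exon_iv, genomic_order = genomic_order,
               cds_truth = setNames(paste(codons, collapse = ""),
                                    tx$transcript_id))
  list(model = model, meta = meta, seq = pieces, cursor = cur)
}

#' Build the worked-example discovery-cohort fixture
#'
#' Writes every input the pipeline consumes to `dir` and returns the
#' paths, a ready [run_discovery_pipeline()] config, and the expected
#' summary values.
#'
#' @param dir Output directory (default a fresh temporary directory).
#' @return List: `paths` (named files), `config` (pipeline config list),
#'   `expected` (printed summary values), `table` (the gene table).
#' @export
discovery_cohort_fixture <- function(dir = tempfile("fixture")) {
  set.seed(FIXTURE_SEED)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- discovery_gene_table()

  extra_genes <- data.frame(
    gene = c("APRI1", "APRI2", "APRI3", "APRI4", "NONCAND1"),
    chrom = "1", apriori = c(TRUE, TRUE, TRUE, TRUE, FALSE))

  models <- list(); meta <- list(); seqs <- list(); cursors <- list()
  add_gene <- function(gene_id, symbol, chrom, n_codons = 16L) {
    cur <- cursors[[chrom]] %||% 0L
    g <- fixture_gene(gene_id, symbol, chrom, cur, n_codons = n_codons,
                      strand = sample(c("+", "-"), 1L))
    models[[gene_id]] <<- g$model
    meta[[gene_id]] <<- g$meta
    seqs[[chrom]] <<- paste0(seqs[[chrom]] %||% "", g$seq)
    cursors[[chrom]] <<- g$cursor
  }
  for (i in seq_len(nrow(tab)))
    add_gene(sprintf("FX%03d", i), tab$gene[i], tab$chrom[i])
  for (i in seq_len(nrow(extra_genes)))
    add_gene(sprintf("EX%03d", i), extra_genes$gene[i], extra_genes$chrom[i],
             n_codons = 40L)
  reference <- vapply(seqs, function(s) paste0(s, strrep("A", 30L)),
                      character(1))
  genome <- structure(list(models = structure(models,
                                              class = "GeneModelSet"),
                           reference = reference, meta = meta),
                      class = "sim_genome")
  state <- plant_state(genome)

  # case cohort: tabulated carriers + filler to 342, + 3 expansion carriers
  table_cases <- unique(tab$case_id)
  n_fill <- 342L - length(table_cases)
  filler <- sprintf("LO8%03d", seq_len(n_fill))
  case_ids <- c(table_cases, filler)
  expansion_cases <- filler[1:3]
  control_cases <- filler[4:7]

  variants <- list(); gt_rows <- list(); panel_rows <- list()
  pred_rows <- list(); patho_rows <- list()
  add_case_variant <- function(gene_id, class, carriers, dosage = 1L,
                               internal_ac = NA_integer_) {
    site <- place_variant(genome, gene_id, class, state)
    if (is.null(site)) stop("fixture: cannot place ", class, " in ", gene_id)
    m <- meta[[gene_id]]
    key <- variant_key(m$chrom, site$pos, site$ref, site$alt)
    variants[[length(variants) + 1L]] <<- data.frame(
      chrom = m$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      key = key)
    gt_rows[[key]] <<- setNames(rep(dosage, length(carriers)), carriers)
    if (!is.na(internal_ac))
      panel_rows[[length(panel_rows) + 1L]] <<- data.frame(
        chrom = m$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
        panel = "internal", alt_count = internal_ac, total_alleles = 10984L)
    panel_rows[[length(panel_rows) + 1L]] <<- data.frame(
      chrom = m$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      panel = "ExAC", alt_count = 0L, total_alleles = 121412L)
    key
  }

  # one case-exclusive non-terminal stopgain per tabulated row
  tab$key <- NA_character_
  for (i in seq_len(nrow(tab))) {
    dosage <- if (tab$mode[i] == "Recessive") 2L else 1L
    tab$key[i] <- add_case_variant(sprintf("FX%03d", i),
                                   "stopgain_nonterminal", tab$case_id[i],
                                   dosage = dosage)
  }

  # working-gene expansion: de novo rare DNS in three de novo LOF genes
  exp_genes <- c("KMT2D", "TBX20", "ZEB2")
  exp_keys <- character(3L)
  for (j in seq_along(exp_genes)) {
    gid <- sprintf("FX%03d", match(exp_genes[j], tab$gene))
    exp_keys[j] <- add_case_variant(gid, "missense_dns", expansion_cases[j],
                                    internal_ac = 2L)
    m <- meta[[gid]]
    v <- variants[[length(variants)]]
    calls <- c("D", "D", "D", "D", "T", "T")[sample.int(6L)]
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      SIFT = calls[1], PolyPhen2_HDIV = calls[2], LRT = calls[3],
      MutationTaster = calls[4], MutationAssessor = calls[5],
      FATHMM = calls[6], cadd_scaled = round(runif(1, 20, 35), 2))
  }

  # funnel negative controls: LOF outside the a-priori list; recurrent LOF
  add_case_variant("EX005", "stopgain_nonterminal", control_cases[1])
  add_case_variant("EX001", "stopgain_nonterminal", control_cases[2:4])

  # known-pathogenic crossref plantings: 14 case-exclusive, 15 MAC < 5,
  # 14 internally too common
  crossref_tiers <- c(rep(NA_integer_, 14L), rep(2L, 15L), rep(100L, 14L))
  for (i in seq_along(crossref_tiers)) {
    gid <- sprintf("EX%03d", (i - 1L) %% 4L + 1L)
    k <- add_case_variant(gid, "missense_nondns",
                          sample(filler, 1L),
                          internal_ac = crossref_tiers[i])
    patho_rows[[length(patho_rows) + 1L]] <- data.frame(
      key = k, source = c("ClinVar", "HGMD")[i %% 2L + 1L])
  }

  variants <- do.call(rbind, variants)
  variants$vclass <- classify_vclass(variants$ref, variants$alt)
  genotypes <- matrix(0L, nrow(variants), length(case_ids),
                      dimnames = list(variants$key, case_ids))
  for (k in names(gt_rows)) genotypes[k, names(gt_rows[[k]])] <- gt_rows[[k]]
  quality <- data.frame(posterior_prob = 0.99, depth = 50L,
                        variant_reads = 25L, allelic_fraction = 0.5,
                        max_strand_fraction = 0.55,
                        is_homref_call = FALSE)[rep(1L, nrow(variants)), ]

  # trio genotypes for tabulated probands and expansion carriers
  trio_probands <- c(table_cases, expansion_cases)
  sexes <- setNames(sample(c("male", "female"), length(trio_probands),
                           replace = TRUE), trio_probands)
  sexes[tab$case_id[tab$mode == "X-linked"]] <- "male"
  single_parent <- unique(tab$case_id[tab$mode == "Unknown"])
  ped <- data.frame(
    family_id = paste0("F", trio_probands), sample_id = trio_probands,
    father_id = ifelse(trio_probands %in% single_parent, "0",
                       paste0(trio_probands, "_F")),
    mother_id = paste0(trio_probands, "_M"),
    sex = ifelse(sexes == "male", 1L, 2L), phenotype = "2")
  parent_cols <- c(ped$father_id[ped$father_id != "0"], ped$mother_id)
  ped <- rbind(ped, data.frame(
    family_id = paste0("F", sub("_[MF]$", "", parent_cols)),
    sample_id = parent_cols, father_id = "0", mother_id = "0",
    sex = ifelse(grepl("_F$", parent_cols), 1L, 2L), phenotype = "1"))
  trio_samples <- c(trio_probands, parent_cols)
  trio_keys <- c(tab$key, exp_keys)
  trio_gt <- matrix(0L, length(trio_keys), length(trio_samples),
                    dimnames = list(trio_keys, trio_samples))
  trio_hemi <- matrix(FALSE, length(trio_keys), length(trio_samples),
                      dimnames = dimnames(trio_gt))
  set_parent <- function(key, sample, g) {
    if (sample %in% colnames(trio_gt)) trio_gt[key, sample] <<- g
  }
  for (i in seq_len(nrow(tab))) {
    case <- tab$case_id[i]; key <- tab$key[i]
    mo <- paste0(case, "_M"); fa <- paste0(case, "_F")
    switch(tab$mode[i],
      "De novo" = { trio_gt[key, case] <- 1L },
      "Inherited" = {
        trio_gt[key, case] <- 1L
        if (case %in% single_parent) set_parent(key, mo, 1L)
        else if (i %% 2L == 0L) set_parent(key, mo, 1L)
        else set_parent(key, fa, 1L)
      },
      "Recessive" = {
        trio_gt[key, case] <- 2L
        set_parent(key, mo, 1L); set_parent(key, fa, 1L)
      },
      "X-linked" = {
        trio_gt[key, case] <- 1L
        trio_hemi[key, case] <- TRUE
        set_parent(key, mo, 1L)
        set_parent(key, fa, 0L)
        if (fa %in% colnames(trio_hemi)) trio_hemi[key, fa] <- TRUE
      },
      "Unknown" = {
        trio_gt[key, case] <- 1L   # mother genotyped non-carrier
      })
  }
  for (j in seq_along(exp_keys))
    trio_gt[exp_keys[j], expansion_cases[j]] <- 1L  # de novo: parents 0

  trio_variants <- variants[match(trio_keys, variants$key), ]
  trio_quality <- quality[match(trio_keys, variants$key), ]

  # clinical cohort flags: 79 carriers (34 with CVM), 755 with CVM overall
  n_clin <- 4778L
  clin <- data.frame(sample = sprintf("BG%04d", seq_len(n_clin)),
                     carrier = rep(c(TRUE, FALSE), c(79L, n_clin - 79L)),
                     phenotype = c(rep(c(TRUE, FALSE), c(34L, 45L)),
                                   rep(c(TRUE, FALSE),
                                       c(721L, n_clin - 79L - 721L))))

  apriori <- rbind(
    data.frame(gene = tab$gene, sources = tab$support),
    data.frame(gene = extra_genes$gene[extra_genes$apriori],
               sources = "CVM"))

  paths <- c(
    write_genome(genome, dir),
    case_vcf = file.path(dir, "cases.vcf"),
    trio_vcf = file.path(dir, "trios.vcf"),
    ped = file.path(dir, "trios.ped"),
    panels = file.path(dir, "panels.tsv"),
    predictors = file.path(dir, "predictors.tsv"),
    apriori = file.path(dir, "apriori_genes.tsv"),
    pathogenic = file.path(dir, "pathogenic.tsv"),
    carrier_flags = file.path(dir, "clinical_flags.tsv"))
  write_vcf(variants, genotypes, quality, paths[["case_vcf"]])
  write_vcf(trio_variants, trio_gt, trio_quality, paths[["trio_vcf"]],
            hemi = trio_hemi)
  write.table(ped, paths[["ped"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  panels <- do.call(rbind, panel_rows)
  write.table(panels, paths[["panels"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  preds <- do.call(rbind, pred_rows)
  write.table(preds, paths[["predictors"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(apriori, paths[["apriori"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  patho <- do.call(rbind, patho_rows)
  patho <- cbind(do.call(rbind, strsplit(patho$key, ":")) |>
                   (\(m) data.frame(chrom = m[, 1L],
                                    pos = as.integer(m[, 2L]),
                                    ref = m[, 3L], alt = m[, 4L]))(),
                 source = patho$source)
  write.table(patho, paths[["pathogenic"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clin, paths[["carrier_flags"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  config <- list(gtf = paths[["gtf"]], fasta = paths[["fasta"]],
                 case_vcf = paths[["case_vcf"]],
                 trio_vcf = paths[["trio_vcf"]], ped = paths[["ped"]],
                 panels = paths[["panels"]],
                 predictors = paths[["predictors"]],
                 apriori = paths[["apriori"]],
                 pathogenic = paths[["pathogenic"]],
                 carrier_flags = paths[["carrier_flags"]],
                 cohort_size = 342L)

  expected <- list(
    n_candidate_genes = 27L,
    n_candidate_variants = 27L,
    carrier_cases_printed = 26L,
    pct_cohort_printed = 7.6,
    carrier_cases_from_table = length(table_cases),
    pct_cohort_from_table = round_half_away(
      100 * length(table_cases) / 342, 1L),
    mode_tally = c(de_novo = 9L, inherited_dominant = 13L,
                   recessive_homozygous = 1L, x_linked = 1L, unknown = 3L),
    n_expansion_dns = 3L,
    odds_ratio = 4.03,
    crossref_tiers = c(case_exclusive_reported = 14L, mac_lt_5 = 15L,
                       high_freq_deprioritized = 14L))

  list(paths = paths, config = config, expected = expected, table = tab,
       genome = genome)
}
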