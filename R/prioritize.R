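# The discovery funnel: rarity tiers, recurrence pruning, constraint
# gating, a-priori candidate-gene intersection, working-gene DNS
# expansion, known-pathogenic cross-reference, and the end-to-end
# orchestrator.
#
# Two rarity gates coexist: the LOF discovery arm requires the variant to
# be absent from the internal comparison panel (case-exclusive), while
# the DNS and crossref arms accept tier "rare" (internal MAF < 0.05%).
# All public-panel MAFs must be < 0.5% in either arm.

APRIORI_SOURCES <- c("CVM", "MGI", "ZFIN", "HE", "TGFB", "PITX2", "SHH",
                     "NOTCH", "CHD_candidate", "PCD")

#' Assign rarity tiers to variants
#'
#' `case_exclusive`: alt allele absent from the internal comparison panel
#' and every public-panel MAF below `public_maf`. `rare`: internal MAF
#' below `internal_maf` and every public-panel MAF below `public_maf`.
#' Otherwise `common`. A variant absent from a panel counts as frequency
#' zero in that panel.
#'
#' @param keys Variant keys (`chrom:pos:ref:alt`).
#' @param panels Frequency table from [read_panels()].
#' @param internal_panel Panel id of the internal comparison cohort.
#' @param public_maf Public-panel MAF ceiling (default 0.005).
#' @param internal_maf Internal MAF ceiling for tier `rare`
#'   (default 0.0005).
#' @return data.frame: key, tier, internal_maf, internal_absent,
#'   max_public_maf.
#' @export
rarity_tier <- function(keys, panels, internal_panel = "internal",
                        public_maf = 0.005, internal_maf = 0.0005) {
  int <- panels[panels$panel == internal_panel, ]
  pub <- panels[panels$panel != internal_panel, ]
  out <- data.frame(key = keys, tier = "common",
                    internal_maf = 0, internal_absent = TRUE,
                    max_public_maf = 0, stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    k <- keys[i]
    irec <- int[int$key == k, ]
    i_ac <- if (nrow(irec)) sum(irec$alt_count) else 0L
    i_maf <- if (nrow(irec) && i_ac > 0)
      panel_maf(sum(irec$alt_count), sum(irec$total_alleles)) else 0
    prec <- pub[pub$key == k, ]
    p_maf <- if (nrow(prec))
      max(panel_maf(prec$alt_count, prec$total_alleles)) else 0
    out$internal_maf[i] <- i_maf
    out$internal_absent[i] <- i_ac == 0L
    out$max_public_maf[i] <- p_maf
    out$tier[i] <- if (i_ac == 0L && p_maf < public_maf) "case_exclusive"
      else if (i_maf < internal_maf && p_maf < public_maf) "rare"
      else "common"
  }
  out
}

#' Prune recurrent LOF sites
#'
#' Removes LOF calls whose site is carried by more than `max_occurrences`
#' cases in the case cohort (ethnic-stratification guard). Occurrences
#' count carrier cases (genotype with >= 1 alt allele), not alleles.
#' Non-LOF (DNS) calls pass through untouched.
#'
#' @param calls data.frame with `key` and `lof_class` columns.
#' @param case_genotypes Alt-allele-count matrix (keys x case samples).
#' @param max_occurrences Default 2 ("seen more than two times" removed).
#' @return Pruned calls; attribute `"removed"` lists pruned keys.
#' @export
recurrence_prune <- function(calls, case_genotypes, max_occurrences = 2L) {
  occ <- function(k) {
    if (!k %in% rownames(case_genotypes)) return(0L)
    sum(case_genotypes[k, ] >= 1L, na.rm = TRUE)
  }
  is_lof <- calls$lof_class != "none" & !is.na(calls$lof_class)
  counts <- vapply(calls$key, occ, integer(1))
  drop <- is_lof & counts > max_occurrences
  structure(calls[!drop, , drop = FALSE],
            removed = unique(calls$key[drop]))
}

#' Read the a-priori candidate gene list
#'
#' TSV with columns `gene` and `sources` (comma-separated evidence tags
#' from the controlled vocabulary: CVM, MGI, ZFIN, HE, TGFB, PITX2, SHH,
#' NOTCH, CHD_candidate, PCD).
#'
#' @param path TSV path.
#' @return data.frame (gene, sources).
#' @export
read_apriori_list <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(p)) stop("a-priori gene list is empty")
  tags <- unique(unlist(strsplit(p$sources, ",")))
  bad <- setdiff(trimws(tags), APRIORI_SOURCES)
  if (length(bad))
    warning("unrecognized a-priori source tags: ", paste(bad, collapse = ", "))
  p
}

#' Restrict calls to the a-priori candidate gene list
#'
#' @param calls data.frame with a `symbol` column.
#' @param apriori data.frame from [read_apriori_list()].
#' @return Calls in listed genes, with an `apriori_sources` column.
#' @export
apriori_intersect <- function(calls, apriori) {
  if (is.null(apriori) || !nrow(apriori)) stop("a-priori gene list is empty")
  j <- match(calls$symbol, apriori$gene)
  out <- calls[!is.na(j), , drop = FALSE]
  out$apriori_sources <- apriori$sources[j[!is.na(j)]]
  out
}

#' Working-gene DNS expansion
#'
#' After de novo LOF genes are identified, emits the rare/case-exclusive
#' DNS calls lying in exactly those genes as expansion candidates.
#'
#' @param denovo_lof_genes Character vector of gene symbols with a de novo
#'   LOF call.
#' @param annotations Annotation table ([annotate_variants()]).
#' @param tiers Rarity tiers ([rarity_tier()]) for the same keys.
#' @return Annotation rows that are DNS, rare or case-exclusive, and in an
#'   expansion gene, with `expansion = TRUE`.
#' @export
working_gene_expansion <- function(denovo_lof_genes, annotations, tiers) {
  if (!length(denovo_lof_genes)) {
    out <- annotations[0, , drop = FALSE]
    out$tier <- character(0); out$expansion <- logical(0)
    return(out)
  }
  t <- tiers$tier[match(annotations$key, tiers$key)]
  sel <- annotations$dns & annotations$symbol %in% denovo_lof_genes &
    t %in% c("rare", "case_exclusive")
  out <- annotations[sel, , drop = FALSE]
  out$tier <- t[sel]
  out$expansion <- rep(TRUE, nrow(out))
  out
}

#' Read a known-pathogenic variant table
#'
#' TSV keyed by chrom, pos, ref, alt with a `source` column (e.g. ClinVar
#' or HGMD extract).
#'
#' @param path TSV path.
#' @return data.frame with a `key` column.
#' @export
read_pathogenic_table <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  p$key <- variant_key(p$chrom, p$pos, p$ref, p$alt)
  p
}

#' Cross-reference case variants with known-pathogenic databases
#'
#' Matched variants are tiered on the internal comparison panel:
#' `case_exclusive_reported` (absent), `mac_lt_5` (minor allele count
#' below 5), `high_freq_deprioritized` (internal MAF above `high_maf`,
#' i.e. more common than expected for a pathogenic allele), else `none`.
#'
#' @param case_keys Variant keys observed in cases.
#' @param pathogenic Table from [read_pathogenic_table()].
#' @param panels Frequency table from [read_panels()].
#' @param internal_panel Internal panel id.
#' @param high_maf Deprioritization MAF (default 0.005).
#' @return data.frame (key, source, internal_mac, internal_maf, tier) for
#'   matched variants; attribute `"tier_counts"` is the per-tier table.
#' @export
known_pathogenic_crossref <- function(case_keys, pathogenic, panels,
                                      internal_panel = "internal",
                                      high_maf = 0.005) {
  hit <- pathogenic[pathogenic$key %in% case_keys, , drop = FALSE]
  int <- panels[panels$panel == internal_panel, ]
  n <- nrow(hit)
  mac <- integer(n); maf <- numeric(n); tier <- character(n)
  for (i in seq_len(n)) {
    irec <- int[int$key == hit$key[i], ]
    ac <- if (nrow(irec)) sum(irec$alt_count) else 0L
    tot <- if (nrow(irec)) sum(irec$total_alleles) else 0L
    mc <- if (tot > 0) min(ac, tot - ac) else ac
    mf <- if (tot > 0) panel_maf(ac, tot) else 0
    mac[i] <- mc; maf[i] <- mf
    tier[i] <- if (ac == 0L) "case_exclusive_reported"
      else if (mf > high_maf) "high_freq_deprioritized"
      else if (mc < 5L) "mac_lt_5"
      else "none"
  }
  out <- data.frame(key = hit$key, source = hit$source,
                    internal_mac = mac, internal_maf = maf, tier = tier,
                    stringsAsFactors = FALSE)
  structure(out, tier_counts = table(factor(tier,
    levels = c("case_exclusive_reported", "mac_lt_5",
               "high_freq_deprioritized", "none"))))
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the discovery pipeline end to end
#'
#' Executes quality control, consequence annotation, rarity tiering,
#' recurrence pruning, constraint gating (advisory by default), a-priori
#' intersection, trio segregation, working-gene DNS expansion,
#' known-pathogenic cross-reference, and clinical-cohort enrichment.
#' Deterministic given its inputs.
#'
#' @param config Named list. Required: `gtf`, `fasta`, `case_vcf`,
#'   `panels`, `apriori` (paths or pre-loaded objects). Optional:
#'   `predictors`, `ped`, `trio_vcf`, `constraint` (precomputed table),
#'   `pathogenic`, `carrier_flags`, `cohort_size`, and thresholds
#'   `public_maf` (0.005), `internal_maf` (0.0005), `dns_min_damaging`
#'   (3), `lof_recurrence_max` (2), `op_percentile` (30),
#'   `internal_panel` ("internal"), `constraint_strict` (FALSE).
#' @param verbose Log per-stage input/output counts via [message()].
#' @return List of class `discovery_report`: `candidates` (per-case LOF
#'   candidate calls with segregation modes), `expansion` (working-gene
#'   DNS calls), `crossref`, `enrichment`, `constraint`, `summary`,
#'   `stage_log`, and `stages` (retained key sets per funnel stage).
#' @export
run_discovery_pipeline <- function(config, verbose = TRUE) {
  cfg <- function(name, default = NULL) config[[name]] %||% default
  stage_log <- list()
  log_stage <- function(stage, n_in, n_out) {
    stage_log[[length(stage_log) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out)
    if (verbose) message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stages <- list()

  models <- run("load_models", resolve_input(config$gtf, load_gene_models))
  reference <- run("load_reference", resolve_input(
    config$fasta, Biostrings::readDNAStringSet))
  if (methods::is(reference, "DNAStringSet"))
    names(reference) <- sub("\\s.*$", "", names(reference))
  ped <- if (!is.null(config$ped)) resolve_input(config$ped, read_ped)
  cases <- run("read_case_vcf", resolve_input(config$case_vcf, read_vcf))
  panels <- run("read_panels", resolve_input(config$panels, read_panels))
  apriori <- run("read_apriori",
                 resolve_input(config$apriori, read_apriori_list))
  predictors <- if (!is.null(config$predictors))
    resolve_input(config$predictors, read_predictors)

  # quality control
  n0 <- nrow(cases$variants)
  qc <- run("qc", {
    is_snv <- cases$variants$vclass == "SNV"
    pass <- logical(n0)
    if (any(is_snv))
      pass[is_snv] <- snv_quality_filter(cases$quality[is_snv, ])$pass
    if (any(!is_snv))
      pass[!is_snv] <- indel_quality_filter(cases$quality[!is_snv, ])$pass
    pass
  })
  variants <- cases$variants[qc, , drop = FALSE]
  genotypes <- cases$genotypes[qc, , drop = FALSE]
  log_stage("qc", n0, nrow(variants))
  stages$qc <- variants$key

  # consequence annotation
  ann <- run("annotate", annotate_variants(
    variants, models, reference, predictors = predictors,
    dns_min_damaging = cfg("dns_min_damaging", 3L)))
  log_stage("annotate", nrow(variants), nrow(ann))
  stages$annotate <- unique(ann$key)

  # rarity tiers
  tiers <- run("rarity", rarity_tier(
    unique(ann$key), panels, internal_panel = cfg("internal_panel", "internal"),
    public_maf = cfg("public_maf", 0.005),
    internal_maf = cfg("internal_maf", 0.0005)))
  ann$tier <- tiers$tier[match(ann$key, tiers$key)]

  # LOF discovery arm: case-exclusive conservative LOF
  lof <- ann[ann$conservative_lof & ann$tier == "case_exclusive", ,
             drop = FALSE]
  log_stage("lof_rarity", nrow(ann), nrow(lof))
  stages$lof_rarity <- unique(lof$key)

  # recurrence pruning
  lof2 <- run("recurrence", recurrence_prune(
    lof, genotypes, max_occurrences = cfg("lof_recurrence_max", 2L)))
  log_stage("recurrence", nrow(lof), nrow(lof2))
  stages$recurrence <- unique(lof2$key)

  # constraint gate (advisory unless constraint_strict)
  constraint <- if (!is.null(config$constraint))
    resolve_input(config$constraint, function(p)
      read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  if (!is.null(constraint)) {
    lof2$constrained <- constraint$constrained[
      match(lof2$gene_id, constraint$gene_id)]
    if (isTRUE(cfg("constraint_strict", FALSE)))
      lof2 <- lof2[!is.na(lof2$constrained) & lof2$constrained, , drop = FALSE]
  } else lof2$constrained <- NA
  log_stage("constraint_gate", length(stages$recurrence),
            length(unique(lof2$key)))
  stages$constraint_gate <- unique(lof2$key)

  # a-priori candidate-gene intersection
  lof3 <- run("apriori", apriori_intersect(lof2, apriori))
  log_stage("apriori", nrow(lof2), nrow(lof3))
  stages$apriori <- unique(lof3$key)

  # per-case candidate calls
  candidates <- run("candidates", {
    rows <- list()
    for (i in seq_len(nrow(lof3))) {
      k <- lof3$key[i]
      if (!k %in% rownames(genotypes)) next
      carriers <- colnames(genotypes)[which(genotypes[k, ] >= 1L)]
      for (case in carriers) {
        r <- lof3[i, , drop = FALSE]
        r$case_id <- case
        rows[[length(rows) + 1L]] <- r
      }
    }
    if (length(rows)) do.call(rbind, rows) else {
      out <- lof3[0, , drop = FALSE]; out$case_id <- character(0); out
    }
  })

  # segregation against trios
  trio <- if (!is.null(config$trio_vcf))
    run("read_trio_vcf", resolve_input(config$trio_vcf, read_vcf))
  if (!is.null(trio) && !is.null(ped) && nrow(candidates)) {
    candidates <- run("segregate",
                      segregate_calls(candidates, trio$genotypes, ped))
  } else if (nrow(candidates)) {
    candidates$mode <- "unresolved"
    candidates$partner_variant <- NA_character_
  } else {
    candidates$mode <- character(0)
    candidates$partner_variant <- character(0)
  }
  log_stage("segregate", nrow(candidates), nrow(candidates))

  # working-gene DNS expansion
  denovo_genes <- unique(candidates$symbol[candidates$mode == "de_novo"])
  expansion <- run("expansion",
                   working_gene_expansion(denovo_genes, ann, tiers))
  if (nrow(expansion) && !is.null(trio) && !is.null(ped)) {
    exp_calls <- list()
    for (i in seq_len(nrow(expansion))) {
      k <- expansion$key[i]
      if (!k %in% rownames(genotypes)) next
      carriers <- colnames(genotypes)[which(genotypes[k, ] >= 1L)]
      for (case in carriers) {
        r <- expansion[i, , drop = FALSE]; r$case_id <- case
        exp_calls[[length(exp_calls) + 1L]] <- r
      }
    }
    expansion <- if (length(exp_calls)) do.call(rbind, exp_calls) else
      { e <- expansion[0, , drop = FALSE]; e$case_id <- character(0); e }
    if (nrow(expansion))
      expansion <- segregate_calls(expansion, trio$genotypes, ped)
  }
  log_stage("expansion", length(denovo_genes), nrow(expansion))

  # known-pathogenic cross-reference
  crossref <- if (!is.null(config$pathogenic)) {
    run("crossref", known_pathogenic_crossref(
      unique(ann$key),
      resolve_input(config$pathogenic, read_pathogenic_table), panels,
      internal_panel = cfg("internal_panel", "internal")))
  }

  # clinical-cohort enrichment
  enrichment <- if (!is.null(config$carrier_flags)) {
    run("enrich", enrichment_report(
      resolve_input(config$carrier_flags, read_carrier_flags)))
  }

  cohort_size <- cfg("cohort_size", ncol(genotypes))
  carrier_cases <- unique(candidates$case_id)
  summary <- list(
    n_candidate_genes = length(unique(candidates$symbol)),
    n_candidate_variants = length(unique(candidates$key)),
    n_candidate_calls = nrow(candidates),
    carrier_cases = length(carrier_cases),
    cohort_size = cohort_size,
    pct_cohort = round_half_away(
      100 * length(carrier_cases) / max(cohort_size, 1L), 1L),
    mode_tally = if (nrow(candidates))
      table(candidates$mode) else table(character(0)),
    n_expansion_dns = nrow(expansion))

  structure(list(candidates = candidates, expansion = expansion,
                 crossref = crossref, enrichment = enrichment,
                 constraint = constraint, annotations = ann, tiers = tiers,
                 summary = summary,
                 stage_log = do.call(rbind, stage_log), stages = stages),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "Discovery report: %d candidate gene(s), %d LOF variant(s) in %d case(s)",
    " (%.1f%% of %d)\n"),
    s$n_candidate_genes, s$n_candidate_variants, s$carrier_cases,
    s$pct_cohort, s$cohort_size))
  if (length(s$mode_tally)) {
    cat("Inheritance modes:\n")
    print(s$mode_tally)
  }
  if (!is.null(x$enrichment))
    cat(sprintf("Clinical-cohort enrichment OR = %.2f (95%% CI %.2f-%.2f)\n",
                x$enrichment$odds_ratio, x$enrichment$ci_lower,
                x$enrichment$ci_upper))
  invisible(x)
}
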