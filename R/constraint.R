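# Gene constraint via the OP ratio: observed LOF alleles in a comparison
# cohort divided by the number of potential LOF substitution sites
# enumerable in the gene. Observed counts are alleles (chromosomes),
# potential counts are (position, alt) pairs, so the ratio is used only
# ordinally (zero / percentile rank), never as a bounded fraction.

#' Enumerate potential LOF substitution sites of a gene
#'
#' Walks every position of the gene's exonic union plus the essential
#' splice positions of all its transcripts, substitutes each of the three
#' non-reference alleles, classifies the substitution, and counts the
#' (position, alt) pairs that qualify as conservative LOF.
#'
#' @param gene A `GeneModel`.
#' @param reference Named chromosome sequences covering the gene span.
#' @param stopgain_all_isoforms See [conservative_lof()].
#' @return Integer count of potential LOF sites; attribute `"sites"` holds
#'   a data.frame of the qualifying (pos, ref, alt, lof_class).
#' @export
enumerate_potential_lof <- function(gene, reference,
                                    stopgain_all_isoforms = TRUE) {
  gctx <- gene_context(gene, reference)
  chromseq <- reference_chrom(reference, gene$chrom)
  positions <- sort(unique(c(exonic_positions(gene),
                             unlist(gctx$tx |> lapply(`[[`, "ess"),
                                    use.names = FALSE))))
  if (length(positions) && max(positions) > nchar(chromseq))
    stop("gene ", gene$gene_id, " extends beyond the reference")
  hits <- list()
  n <- 0L
  ess_all <- gctx$ess_all
  for (pos in positions) {
    refb <- substr(chromseq, pos, pos)
    if (length(ess_all) && pos %in% ess_all) {
      # any substitution at an all-isoform essential site is splice LOF
      for (altb in setdiff(DNA_BASES, refb)) {
        n <- n + 1L
        hits[[n]] <- data.frame(pos = pos, ref = refb, alt = altb,
                                lof_class = "splice_lof")
      }
      next
    }
    cds_ctx <- Filter(function(ctx) !is.na(match(pos, ctx$cds_pos)), gctx$tx)
    if (!length(cds_ctx)) next
    for (altb in setdiff(DNA_BASES, refb)) {
      ok <- vapply(cds_ctx, function(ctx) {
        r <- classify_snv_ctx(pos, refb, altb, ctx, gene$strand)
        r$category == "stopgain" && isTRUE(!r$is_terminal_coding_exon)
      }, logical(1))
      hit <- if (stopgain_all_isoforms) all(ok) else any(ok)
      if (hit) {
        n <- n + 1L
        hits[[n]] <- data.frame(pos = pos, ref = refb, alt = altb,
                                lof_class = "stopgain_lof")
      }
    }
  }
  structure(n, sites = if (n) do.call(rbind, hits) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               lof_class = character(0)))
}

#' Count observed LOF alleles of a gene in a comparison cohort
#'
#' Sums alt-allele counts (het = 1, hom-alt = 2, hemizygous = 1) over all
#' conservative-LOF variants of the gene across all comparison samples.
#'
#' @param gene_id Gene identifier.
#' @param annotations Annotation table from [annotate_variants()] for the
#'   comparison cohort's variants.
#' @param genotypes Integer matrix of alt-allele counts (variants keyed by
#'   rowname x samples).
#' @return Integer allele count.
#' @export
observed_lof_alleles <- function(gene_id, annotations, genotypes) {
  if (!gene_id %in% annotations$gene_id)
    stop("gene ", gene_id, " absent from annotations")
  keys <- annotations$key[annotations$gene_id == gene_id &
                          annotations$conservative_lof]
  keys <- intersect(keys, rownames(genotypes))
  if (!length(keys)) return(0L)
  sum(genotypes[keys, , drop = FALSE], na.rm = TRUE)
}

#' Build the gene-constraint table
#'
#' @param genes `GeneModelSet` (the ranking universe).
#' @param reference Named chromosome sequences.
#' @param annotations,genotypes Comparison-cohort annotation table and
#'   genotype matrix (see [observed_lof_alleles()]); genes without any
#'   annotated variant count 0 observed alleles.
#' @param percentile_threshold Constraint percentile cutoff (default 30).
#' @param external Optional data.frame (gene_id, pli, rvis) joined as
#'   pass-through reference columns, never used as filters.
#' @return data.frame: gene_id, observed_lof_alleles, potential_lof_sites,
#'   op_ratio, percentile, constrained, pli_reference, rvis_reference.
#' @export
gene_constraint_table <- function(genes, reference, annotations, genotypes,
                                  percentile_threshold = 30,
                                  external = NULL) {
  tab <- do.call(rbind, lapply(genes, function(g) {
    pot <- as.integer(enumerate_potential_lof(g, reference))
    obs <- if (g$gene_id %in% annotations$gene_id)
      observed_lof_alleles(g$gene_id, annotations, genotypes) else 0L
    data.frame(gene_id = g$gene_id, observed_lof_alleles = obs,
               potential_lof_sites = pot, row.names = NULL)
  }))
  tab$op_ratio <- ifelse(tab$potential_lof_sites > 0,
                         tab$observed_lof_alleles / tab$potential_lof_sites,
                         NA_real_)
  tab <- op_percentiles(tab, percentile_threshold = percentile_threshold)
  tab$pli_reference <- NA_real_
  tab$rvis_reference <- NA_real_
  if (!is.null(external)) {
    j <- match(tab$gene_id, external$gene_id)
    if ("pli" %in% colnames(external)) tab$pli_reference <- external$pli[j]
    if ("rvis" %in% colnames(external)) tab$rvis_reference <- external$rvis[j]
  }
  tab
}

#' Percentile-rank OP ratios and flag constrained genes
#'
#' Percentile of a gene is 100 x (number of scored genes with a strictly
#' smaller OP ratio) / (number of scored genes); ties share the lower
#' rank. A gene is constrained when its OP ratio is zero or its percentile
#' is at or below the threshold. Genes with no potential LOF site are
#' excluded from the ranking (percentile and constrained stay NA).
#'
#' @param constraints data.frame with at least gene_id, op_ratio (NA for
#'   unscored genes).
#' @param percentile_threshold Default 30.
#' @return Input with `percentile` and `constrained` columns updated.
#' @export
op_percentiles <- function(constraints, percentile_threshold = 30) {
  scored <- which(!is.na(constraints$op_ratio))
  if (!length(scored)) stop("no gene with potential LOF sites to rank")
  r <- constraints$op_ratio[scored]
  pct <- vapply(r, function(x) 100 * sum(r < x) / length(r), numeric(1))
  constraints$percentile <- NA_real_
  constraints$percentile[scored] <- pct
  constraints$constrained <- NA
  constraints$constrained[scored] <-
    r == 0 | pct <= percentile_threshold
  constraints
}

#' Write the constraint table to TSV
#'
#' @param constraints Table from [gene_constraint_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraint_table <- function(constraints, path) {
  write.table(constraints, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
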