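# Per-transcript functional classification and the conservative-LOF /
# consensus-DNS definitions.
#
# Conservative LOF keeps only: premature stopgains in a non-terminal coding
# exon, essential-splice disruptions used by all gene isoforms, and
# frameshift indels mapping to all isoforms. DNS is a missense variant
# called damaging by a consensus of the six predictors (default >= 3);
# CADD is carried through but never used to exclude.

PREDICTOR_NAMES <- c("SIFT", "PolyPhen2_HDIV", "LRT", "MutationTaster",
                     "MutationAssessor", "FATHMM")

# Per-transcript lookup structures reused across variants of one gene.
transcript_context <- function(tx, gene, reference) {
  n_ex <- nrow(tx$exons)
  exon_order <- if (gene$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  # exon_order[i] = transcription-order index of genomic exon i
  cds_exon_genomic <- which(vapply(seq_len(n_ex), function(i)
    intervals_overlap_range(tx$cds, tx$exons$start[i], tx$exons$end[i]),
    logical(1)))
  terminal_coding_exon <- if (length(cds_exon_genomic))
    max(exon_order[cds_exon_genomic]) else NA_integer_
  cds_str <- if (nrow(tx$cds)) coding_sequence(tx, reference, gene$chrom,
                                               gene$strand) else ""
  cds_pos <- interval_positions(tx$cds)  # genomic ascending
  cds_idx <- if (length(cds_pos)) {
    if (gene$strand == "+") seq_along(cds_pos) else rev(seq_along(cds_pos))
  } else integer(0)
  intr <- transcript_introns(tx)
  ess <- if (nrow(intr)) sort(unique(c(intr$start, intr$start + 1L,
                                       intr$end - 1L, intr$end))) else integer(0)
  list(tx = tx, exon_order = exon_order,
       terminal_coding_exon = terminal_coding_exon,
       cds_str = cds_str, n_codons = nchar(cds_str) %/% 3L,
       cds_pos = cds_pos, cds_idx = cds_idx, ess = ess,
       span = c(min(tx$exons$start), max(tx$exons$end)))
}

gene_context <- function(gene, reference) {
  ctxs <- lapply(gene$transcripts, transcript_context, gene = gene,
                 reference = reference)
  list(gene = gene, tx = ctxs,
       ess_all = Reduce(intersect, lapply(ctxs, `[[`, "ess")),
       span = c(min(vapply(ctxs, function(c) c$span[1L], numeric(1))),
                max(vapply(ctxs, function(c) c$span[2L], numeric(1)))))
}

exon_index_of <- function(ctx, pos) {
  hit <- which(ctx$tx$exons$start <= pos & ctx$tx$exons$end >= pos)
  if (length(hit)) ctx$exon_order[hit[1L]] else NA_integer_
}

#' Classify an SNV against one transcript
#'
#' Determines the coding consequence by mutating the transcript's CDS
#' string and comparing codon translations. Positions in the transcript's
#' essential splice set classify as `splice_essential`; positions inside
#' the CDS as `stopgain`/`missense`/`synonymous` (start-loss and stop-loss
#' fall into `other`); everything else is `noncoding`.
#'
#' @param variant One-row variant data.frame (SNV).
#' @param transcript A `Transcript` belonging to `gene`.
#' @param gene The `GeneModel` providing chrom/strand context.
#' @param reference Named chromosome sequences.
#' @return List with transcript_id, category, exon_index (transcription
#'   order; NA off-exon), is_terminal_coding_exon, and cds_hit flag.
#' @export
classify_snv <- function(variant, transcript, gene, reference) {
  ctx <- transcript_context(transcript, gene, reference)
  classify_snv_ctx(variant$pos, variant$ref, variant$alt, ctx, gene$strand)
}

classify_snv_ctx <- function(pos, ref, alt, ctx, strand) {
  out <- list(transcript_id = ctx$tx$transcript_id, category = "noncoding",
              exon_index = NA_integer_, is_terminal_coding_exon = NA,
              cds_hit = FALSE)
  if (pos %in% ctx$ess) {
    out$category <- "splice_essential"
    return(out)
  }
  m <- match(pos, ctx$cds_pos)
  if (!is.na(m)) {
    idx <- ctx$cds_idx[m]
    tx_alt <- if (strand == "+") alt else comp_base(alt)
    codon_num <- (idx - 1L) %/% 3L + 1L
    off <- (idx - 1L) %% 3L + 1L
    old_codon <- codon_at(ctx$cds_str, codon_num)
    new_codon <- old_codon
    substr(new_codon, off, off) <- tx_alt
    old_stop <- old_codon %in% STOP_CODONS
    new_stop <- new_codon %in% STOP_CODONS
    old_aa <- aa_one(old_codon)
    new_aa <- aa_one(new_codon)
    out$cds_hit <- TRUE
    out$exon_index <- exon_index_of(ctx, pos)
    out$is_terminal_coding_exon <- identical(out$exon_index,
                                             ctx$terminal_coding_exon)
    out$category <-
      if (old_stop && new_stop) "synonymous"
      else if (old_stop) "other"                       # stop-loss
      else if (new_stop && codon_num < ctx$n_codons) "stopgain"
      else if (new_stop) "other"
      else if (codon_num == 1L && old_aa != new_aa) "other"  # start-loss
      else if (old_aa == new_aa) "synonymous"
      else "missense"
    return(out)
  }
  if (pos >= ctx$span[1L] && pos <= ctx$span[2L]) {
    out$exon_index <- exon_index_of(ctx, pos)
    out$category <- "noncoding"
  }
  out
}

# genomic interval disturbed by an indel (normalized, anchored)
indel_affected_range <- function(pos, ref, alt) {
  if (nchar(ref) > nchar(alt)) c(pos + 1L, pos + nchar(ref) - 1L)  # deletion
  else c(pos, pos + 1L)                                            # insertion
}

#' Classify a small indel against one transcript
#'
#' `frameshift` if the indel disturbs the CDS and the length change is not
#' a multiple of 3; `inframe_indel` if it is; `splice_essential` if it
#' overlaps the transcript's essential splice positions without touching
#' CDS; otherwise `noncoding`.
#'
#' @inheritParams classify_snv
#' @return List as for [classify_snv()].
#' @export
classify_indel <- function(variant, transcript, gene, reference = NULL) {
  ctx <- transcript_context(transcript, gene,
                            reference %||% stub_reference(gene, transcript))
  classify_indel_ctx(variant$pos, variant$ref, variant$alt, ctx)
}

# classify_indel needs no sequence; supply an all-N chromosome when absent
stub_reference <- function(gene, transcript) {
  len <- max(transcript$exons$end) + 10L
  setNames(list(strrep("N", len)), gene$chrom)
}

classify_indel_ctx <- function(pos, ref, alt, ctx) {
  out <- list(transcript_id = ctx$tx$transcript_id, category = "noncoding",
              exon_index = NA_integer_, is_terminal_coding_exon = NA,
              cds_hit = FALSE)
  rng <- indel_affected_range(pos, ref, alt)
  shift <- abs(nchar(ref) - nchar(alt))
  cds_overlap <- if (nchar(ref) > nchar(alt)) {
    nrow(ctx$tx$cds) > 0L &&
      intervals_overlap_range(ctx$tx$cds, rng[1L], rng[2L])
  } else {
    # insertion disturbs coding sequence only if it lands inside a CDS
    # interval (both flanking bases coding in the same interval)
    any(ctx$tx$cds$start <= rng[1L] & ctx$tx$cds$end >= rng[2L])
  }
  if (cds_overlap) {
    out$cds_hit <- TRUE
    out$exon_index <- exon_index_of(ctx, pos)
    if (is.na(out$exon_index)) out$exon_index <- exon_index_of(ctx, rng[1L])
    out$is_terminal_coding_exon <- identical(out$exon_index,
                                             ctx$terminal_coding_exon)
    out$category <- if (shift %% 3L != 0L) "frameshift" else "inframe_indel"
    return(out)
  }
  if (length(ctx$ess) && any(ctx$ess >= rng[1L] & ctx$ess <= rng[2L])) {
    out$category <- "splice_essential"
    return(out)
  }
  if (rng[2L] >= ctx$span[1L] && rng[1L] <= ctx$span[2L])
    out$exon_index <- exon_index_of(ctx, pos)
  out
}

#' Conservative loss-of-function call for a variant in a gene
#'
#' Combines per-transcript consequences under the conservative rules:
#' `stopgain_lof` requires a premature stopgain in a non-terminal coding
#' exon of every CDS-overlapping transcript (all-isoform requirement
#' switchable via `stopgain_all_isoforms`); `splice_lof` requires the
#' position to be an essential splice position of every transcript of the
#' gene; `frameshift_lof` requires a frameshift in every CDS-bearing
#' transcript.
#'
#' @param variant One-row variant data.frame.
#' @param gene The `GeneModel`.
#' @param per_transcript List of per-transcript classifications covering
#'   all transcripts of the gene ([classify_snv()]/[classify_indel()]).
#' @param reference Named chromosome sequences (splice-set computation).
#' @param stopgain_all_isoforms If `TRUE` (default) every CDS-overlapping
#'   transcript must show the non-terminal stopgain; if `FALSE` one
#'   suffices.
#' @return List with `conservative_lof` (logical) and `lof_class` in
#'   `{stopgain_lof, splice_lof, frameshift_lof, none}`.
#' @export
conservative_lof <- function(variant, gene, per_transcript, reference = NULL,
                             stopgain_all_isoforms = TRUE) {
  if (length(per_transcript) == 0L)
    stop("per_transcript must cover the transcripts of ", gene$gene_id)
  cats <- vapply(per_transcript, `[[`, "", "category")
  cds_hits <- vapply(per_transcript, function(x) isTRUE(x$cds_hit), logical(1))
  nonterm <- vapply(per_transcript, function(x)
    isTRUE(!x$is_terminal_coding_exon), logical(1))
  ess <- essential_splice_positions(gene)

  if (variant$vclass == "SNV") {
    if (length(ess$all_isoform) && variant$pos %in% ess$all_isoform)
      return(list(conservative_lof = TRUE, lof_class = "splice_lof"))
    hit <- which(cds_hits)
    if (length(hit)) {
      ok <- cats[hit] == "stopgain" & nonterm[hit]
      if ((stopgain_all_isoforms && all(ok)) ||
          (!stopgain_all_isoforms && any(ok)))
        return(list(conservative_lof = TRUE, lof_class = "stopgain_lof"))
    }
    return(list(conservative_lof = FALSE, lof_class = "none"))
  }

  if (variant$vclass %in% c("insertion", "deletion")) {
    rng <- indel_affected_range(variant$pos, variant$ref, variant$alt)
    in_all <- all(vapply(ess$per_transcript, function(p)
      length(p) > 0L && any(p >= rng[1L] & p <= rng[2L]), logical(1)))
    if (in_all)
      return(list(conservative_lof = TRUE, lof_class = "splice_lof"))
    coding_txs <- vapply(gene$transcripts, function(t) nrow(t$cds) > 0L,
                         logical(1))
    if (any(coding_txs) && all(cats[coding_txs] == "frameshift"))
      return(list(conservative_lof = TRUE, lof_class = "frameshift_lof"))
  }
  list(conservative_lof = FALSE, lof_class = "none")
}

#' Damaging-missense consensus call
#'
#' A missense variant is DNS when at least `min_damaging` of the six
#' predictor calls (SIFT, PolyPhen2-HDIV, LRT, MutationTaster,
#' MutationAssessor, FATHMM) are damaging. Missing calls count as not
#' damaging. The CADD score is recorded alongside but never used as an
#' exclusion criterion.
#'
#' @param calls Named character vector over the six predictors with values
#'   in `{"damaging", "tolerated", "missing"}` (or `{"D", "T", "."}`).
#' @param min_damaging Consensus threshold (default 3).
#' @return Logical.
#' @export
dns_consensus <- function(calls, min_damaging = 3L) {
  if (!setequal(names(calls), PREDICTOR_NAMES))
    stop("calls must be named by the six predictors: ",
         paste(PREDICTOR_NAMES, collapse = ", "))
  calls <- calls[PREDICTOR_NAMES]
  sum(calls %in% c("damaging", "D")) >= min_damaging
}

#' Read a predictor-call table
#'
#' TSV keyed by chrom, pos, ref, alt with one column per predictor (values
#' `D`, `T`, `.`) plus `cadd_scaled`.
#'
#' @param path TSV path.
#' @return data.frame with a `key` column.
#' @export
read_predictors <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = character(0))
  missing_cols <- setdiff(PREDICTOR_NAMES, colnames(p))
  if (length(missing_cols))
    stop("predictor table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  p$key <- variant_key(p$chrom, p$pos, p$ref, p$alt)
  p
}

#' Annotate variants against gene models
#'
#' Classifies every variant against every overlapping gene and applies the
#' conservative-LOF and consensus-DNS definitions. DNS is evaluated only
#' for non-LOF variants that are missense in at least one transcript.
#'
#' @param variants Variant data.frame ([read_vcf()] layout).
#' @param models `GeneModelSet`.
#' @param reference Named chromosome sequences.
#' @param predictors Optional predictor table ([read_predictors()]).
#' @param dns_min_damaging DNS consensus threshold (default 3).
#' @param stopgain_all_isoforms See [conservative_lof()].
#' @return data.frame with one row per (variant, overlapping gene):
#'   key, gene_id, symbol, category (most severe across transcripts),
#'   conservative_lof, lof_class, dns, cadd_scaled.
#' @export
annotate_variants <- function(variants, models, reference, predictors = NULL,
                              dns_min_damaging = 3L,
                              stopgain_all_isoforms = TRUE) {
  rows <- list()
  severity <- c("stopgain", "frameshift", "splice_essential", "missense",
                "inframe_indel", "synonymous", "other", "noncoding")
  for (gene in models) {
    gctx <- gene_context(gene, reference)
    lo <- gctx$span[1L] - 10L; hi <- gctx$span[2L] + 10L
    sel <- which(variants$chrom == gene$chrom & variants$pos >= lo &
                 variants$pos <= hi)
    for (i in sel) {
      v <- variants[i, ]
      if (v$vclass == "MNV") {
        warning("MNV ", v$key, " classified as 'other'")
        per_tx <- lapply(gctx$tx, function(ctx)
          list(transcript_id = ctx$tx$transcript_id, category = "other",
               exon_index = NA_integer_, is_terminal_coding_exon = NA,
               cds_hit = FALSE))
      } else if (v$vclass == "SNV") {
        per_tx <- lapply(gctx$tx, function(ctx)
          classify_snv_ctx(v$pos, v$ref, v$alt, ctx, gene$strand))
      } else {
        per_tx <- lapply(gctx$tx, function(ctx)
          classify_indel_ctx(v$pos, v$ref, v$alt, ctx))
      }
      cats <- vapply(per_tx, `[[`, "", "category")
      if (all(cats == "noncoding") &&
          !(v$pos >= gctx$span[1L] && v$pos <= gctx$span[2L])) next
      lof <- if (v$vclass == "MNV")
        list(conservative_lof = FALSE, lof_class = "none")
      else conservative_lof(v, gene, per_tx, reference,
                            stopgain_all_isoforms = stopgain_all_isoforms)
      dns <- FALSE; cadd <- NA_real_
      if (!is.null(predictors)) {
        j <- match(v$key, predictors$key)
        if (!is.na(j)) {
          cadd <- suppressWarnings(as.numeric(predictors$cadd_scaled[j]))
          if (!lof$conservative_lof && any(cats == "missense")) {
            calls <- vapply(PREDICTOR_NAMES, function(p)
              as.character(predictors[[p]][j]), "")
            dns <- dns_consensus(calls, min_damaging = dns_min_damaging)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        key = v$key, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        vclass = v$vclass, gene_id = gene$gene_id, symbol = gene$symbol,
        category = severity[min(match(cats, severity))],
        conservative_lof = lof$conservative_lof, lof_class = lof$lof_class,
        dns = dns, cadd_scaled = cadd, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(key = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vclass = character(0),
                      gene_id = character(0), symbol = character(0),
                      category = character(0), conservative_lof = logical(0),
                      lof_class = character(0), dns = logical(0),
                      cadd_scaled = numeric(0)))
  do.call(rbind, rows)
}
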