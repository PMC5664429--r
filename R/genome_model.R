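# Gene-model representation.
#
# All stored coordinates are genomic, 1-based, inclusive (GTF/VCF convention);
# strand orientation is applied only when nucleotide strings are built. Exon
# and CDS intervals are kept sorted by genomic start regardless of strand.

#' Construct a transcript
#'
#' @param transcript_id Transcript identifier.
#' @param exons data.frame with `start`, `end` (1-based inclusive, genomic),
#'   non-overlapping.
#' @param cds data.frame with `start`, `end`; every CDS interval must be
#'   contained in exactly one exon and total CDS length must be a multiple
#'   of 3. May be empty (non-coding transcript).
#' @return An object of class `Transcript`.
#' @export
new_transcript <- function(transcript_id, exons, cds = exons[0, , drop = FALSE]) {
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  if (nrow(cds) > 0L) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    rownames(cds) <- NULL
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      sum(exons$start <= cds$start[i] & exons$end >= cds$end[i]) == 1L
    }, logical(1))
    if (!all(contained))
      stop("CDS interval not contained in exactly one exon of transcript ",
           transcript_id)
    len <- sum(cds$end - cds$start + 1L)
    if (len %% 3L != 0L)
      stop("CDS length of transcript ", transcript_id,
           " (", len, ") is not a multiple of 3")
  }
  structure(list(transcript_id = transcript_id, exons = exons, cds = cds),
            class = "Transcript")
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier (unique within a model set).
#' @param symbol Gene symbol.
#' @param chrom Chromosome name shared by all transcripts.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of [new_transcript()] objects (at least one).
#' @return An object of class `GeneModel`.
#' @export
new_gene_model <- function(gene_id, symbol, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1L)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, transcripts = transcripts),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%s, %d transcript(s)\n",
              x$gene_id, x$symbol, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

#' Load gene models from a GTF/GFF3 file
#'
#' Parses exon and CDS features (via `rtracklayer`) into a named list of
#' [new_gene_model()] objects. Transcripts whose total CDS length is not a
#' multiple of 3, or whose CDS escapes its exons, are rejected with an error
#' naming the transcript.
#'
#' @param path GTF or GFF3 file; exon/CDS features must carry `gene_id` and
#'   `transcript_id` attributes (GTF) or equivalent GFF3 attributes.
#' @return Named list (by `gene_id`) of `GeneModel` objects, class
#'   `GeneModelSet`.
#' @export
load_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse gene-model file ",
                                          path, ": ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% colnames(md)))
    stop("gene-model file lacks gene_id/transcript_id attributes")
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    symbol = if ("gene_name" %in% colnames(md))
      as.character(md$gene_name) else as.character(md$gene_id),
    stringsAsFactors = FALSE)
  models <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(t) {
      new_transcript(t$transcript_id[1L],
                     exons = t[t$type == "exon", c("start", "end")],
                     cds = t[t$type == "CDS", c("start", "end")])
    })
    if (length(unique(g$chrom)) != 1L || length(unique(g$strand)) != 1L)
      stop("gene ", g$gene_id[1L], " spans multiple chromosomes or strands")
    new_gene_model(g$gene_id[1L], g$symbol[1L], g$chrom[1L], g$strand[1L], txs)
  })
  structure(models, class = "GeneModelSet")
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the CDS intervals in transcription order and returns the
#' 5'→3' nucleotide string (minus-strand transcripts are reverse
#' complemented).
#'
#' @param transcript A `Transcript`.
#' @param reference Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param chrom Chromosome the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string of length equal to the summed CDS lengths.
#' @export
coding_sequence <- function(transcript, reference, chrom, strand) {
  cds <- transcript$cds
  if (nrow(cds) == 0L) return("")
  chromseq <- reference_chrom(reference, chrom)
  if (max(cds$end) > nchar(chromseq) || min(cds$start) < 1L)
    stop("CDS position outside reference for ", transcript$transcript_id)
  parts <- vapply(seq_len(nrow(cds)),
                  function(i) substr(chromseq, cds$start[i], cds$end[i]), "")
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

reference_chrom <- function(reference, chrom) {
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) stop("chromosome ", chrom,
                                           " absent from reference")
    return(as.character(reference[[chrom]]))
  }
  if (!chrom %in% names(reference)) stop("chromosome ", chrom,
                                         " absent from reference")
  reference[[chrom]]
}

# introns of a transcript as data.frame(start, end), genomic order
transcript_introns <- function(transcript) {
  ex <- transcript$exons
  if (nrow(ex) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' Essential splice positions of a gene
#'
#' The essential splice set of a transcript is the first two and last two
#' bases of each of its introns (donor +1/+2, acceptor -1/-2). The
#' gene-level all-isoform set contains the positions that are essential in
#' every transcript of the gene.
#'
#' @param gene A `GeneModel`.
#' @return List with `per_transcript` (named list of integer position
#'   vectors) and `all_isoform` (integer vector; intersection over all
#'   transcripts).
#' @export
essential_splice_positions <- function(gene) {
  per_tx <- lapply(gene$transcripts, function(tx) {
    intr <- transcript_introns(tx)
    if (nrow(intr) == 0L) return(integer(0))
    sort(unique(c(intr$start, intr$start + 1L, intr$end - 1L, intr$end)))
  })
  all_iso <- Reduce(intersect, per_tx)
  list(per_transcript = per_tx, all_isoform = sort(all_iso))
}

#' Exonic positions of a gene
#'
#' Union of all exon intervals over all transcripts of the gene.
#'
#' @param gene A `GeneModel`.
#' @return Sorted integer vector of genomic positions.
#' @export
exonic_positions <- function(gene) {
  sort(unique(unlist(lapply(gene$transcripts, function(tx)
    interval_positions(tx$exons)), use.names = FALSE)))
}

#' Summarize a gene-model set
#'
#' @param models A `GeneModelSet`.
#' @return data.frame with gene, transcript count, exon count (union), and
#'   per-gene maximum CDS length.
#' @export
gene_model_summary <- function(models) {
  do.call(rbind, lapply(models, function(g) {
    data.frame(gene_id = g$gene_id, symbol = g$symbol, chrom = g$chrom,
               n_transcripts = length(g$transcripts),
               n_exons = length(unique(unlist(lapply(g$transcripts, function(t)
                 paste(t$exons$start, t$exons$end))))),
               max_cds_len = max(vapply(g$transcripts, function(t)
                 sum(t$cds$end - t$cds$start + 1L), integer(1))),
               row.names = NULL)
  }))
}

#' Write a gene-model set to GTF
#'
#' @param models A `GeneModelSet`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in models) {
    for (tx in g$transcripts) {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                          g$gene_id, tx$transcript_id, g$symbol)
      for (i in seq_len(nrow(tx$exons)))
        writeLines(paste(g$chrom, "lofprior", "exon", tx$exons$start[i],
                         tx$exons$end[i], ".", g$strand, ".", attr_str,
                         sep = "\t"), con)
      for (i in seq_len(nrow(tx$cds)))
        writeLines(paste(g$chrom, "lofprior", "CDS", tx$cds$start[i],
                         tx$cds$end[i], ".", g$strand, "0", attr_str,
                         sep = "\t"), con)
    }
  }
  invisible(path)
}
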