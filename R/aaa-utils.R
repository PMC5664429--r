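#' @keywords internal
"_PACKAGE"

#' @import Biostrings
#' @import IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom S4Vectors mcols
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.table write.table
NULL

# Variant keys are "chrom:pos:ref:alt" throughout; coordinates 1-based.

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @return `"chrom:pos:ref:alt"` string(s).
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(COMPLEMENT[x])

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# standard genetic code as a plain lookup (fast path for single codons)
GC_TABLE <- Biostrings::GENETIC_CODE

aa_one <- function(codon) GC_TABLE[[codon]]

#' Translate a coding sequence to amino acids
#'
#' Standard-code translation used by the consequence classifier. Stop codons
#' translate to `*`.
#'
#' @param cds A nucleotide string whose length is a multiple of 3.
#' @return Single-character amino-acid string.
#' @keywords internal
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

codon_at <- function(cds, codon_num) {
  substr(cds, 3L * (codon_num - 1L) + 1L, 3L * codon_num)
}

# round-half-away-from-zero to `digits` decimals; base round() is banker's
round_half_away <- function(x, digits = 1L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# positions covered by a set of [start,end] intervals (data.frame)
interval_positions <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv$start[i], iv$end[i])),
         use.names = FALSE)
}

intervals_overlap_point <- function(iv, pos) {
  any(iv$start <= pos & iv$end >= pos)
}

intervals_overlap_range <- function(iv, lo, hi) {
  any(iv$start <= hi & iv$end >= lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
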