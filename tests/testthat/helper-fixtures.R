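# Small hand-built fixtures shared across test files, plus one cached
# synthetic simulation (building it once keeps the suite fast).

# plus-strand gene: 3 exons, fully coding, CDS "ATG CGA CAA GGG TGC TAA"
# split 6|6|6 across exons at 11-16, 31-36, 51-56
hand_gene_plus <- function() {
  chromseq <- paste0(strrep("T", 10), "ATGCGA", strrep("T", 14), "CAAGGG",
                     strrep("T", 14), "TGCTAA", strrep("T", 10))
  ex <- data.frame(start = c(11L, 31L, 51L), end = c(16L, 36L, 56L))
  tx <- new_transcript("hp.t1", ex, ex)
  gene <- new_gene_model("hp", "HP", "chrT", "+", list(tx))
  list(gene = gene, reference = c(chrT = chromseq))
}

# minus-strand version of the same CDS: genomic content holds the reverse
# complement, transcription runs right to left
hand_gene_minus <- function() {
  cds <- "ATGCGACAAGGGTGCTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  chromseq <- paste0(strrep("T", 10), substr(rc, 1, 6), strrep("T", 14),
                     substr(rc, 7, 12), strrep("T", 14), substr(rc, 13, 18),
                     strrep("T", 10))
  ex <- data.frame(start = c(11L, 31L, 51L), end = c(16L, 36L, 56L))
  tx <- new_transcript("hm.t1", ex, ex)
  gene <- new_gene_model("hm", "HM", "chrT", "-", list(tx))
  list(gene = gene, reference = c(chrT = chromseq))
}

# two-isoform gene sharing intron A; isoform 2 skips the middle exon, so
# the exon-flanking sites of the full isoform are partial-isoform sites
hand_gene_two_isoform <- function() {
  chromseq <- paste0(strrep("T", 10), "ATGCGA", strrep("T", 14), "CAAGGG",
                     strrep("T", 14), "TGCTAA", strrep("T", 10))
  ex_full <- data.frame(start = c(11L, 31L, 51L), end = c(16L, 36L, 56L))
  ex_skip <- data.frame(start = c(11L, 51L), end = c(16L, 56L))
  tx1 <- new_transcript("ti.t1", ex_full, ex_full)
  tx2 <- new_transcript("ti.t2", ex_skip, ex_skip)
  gene <- new_gene_model("ti", "TI", "chrT", "+", list(tx1, tx2))
  list(gene = gene, reference = c(chrT = chromseq))
}

# a coding sequence none of whose non-terminal codons is one substitution
# away from a stop (GGG/CCC are Hamming distance >= 2 from TAA/TAG/TGA)
hand_gene_no_stopgain <- function(n_exons = 1L) {
  cds <- paste0("ATG", strrep("GGGCCC", 3), "TAA")   # 8 codons
  if (n_exons == 1L) {
    chromseq <- paste0(strrep("T", 10), cds, strrep("T", 10))
    ex <- data.frame(start = 11L, end = 10L + nchar(cds))
  } else {
    half <- nchar(cds) / 2
    chromseq <- paste0(strrep("T", 10), substr(cds, 1, half),
                       strrep("T", 30), substr(cds, half + 1, nchar(cds)),
                       strrep("T", 10))
    ex <- data.frame(start = c(11L, 11L + half + 30L),
                     end = c(10L + half, 10L + half + 30L + half))
  }
  tx <- new_transcript("ns.t1", ex, ex)
  gene <- new_gene_model("ns", "NS", "chrT", "+", list(tx))
  list(gene = gene, reference = c(chrT = chromseq))
}

shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(seed = 101L, n_genes = 50L, n_cases = 60L)
      genome <- simulate_genome(spec)
      planted <- plant_variants(spec, genome)
      cache <<- list(spec = spec, genome = genome, planted = planted)
    }
    cache
  }
})
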