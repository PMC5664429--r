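# Independent brute-force oracles. These deliberately avoid the package's
# classification code paths: translation uses a hand-written codon table,
# splicing/mutation work on raw chromosome strings, and LOF rules are
# re-derived from first principles.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3L
  paste(vapply(seq_len(n), function(i)
    ORACLE_CODONS[[substr(s, 3L * i - 2L, 3L * i)]], ""), collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# essential splice positions of one transcript, from exon intervals alone
oracle_splice_sites <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), ]
  if (nrow(ex) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(ex) - 1L)) {
    s <- ex$end[i] + 1L; e <- ex$start[i + 1L] - 1L
    out <- c(out, s, s + 1L, e - 1L, e)
  }
  sort(unique(out))
}

oracle_extract_cds <- function(tx, chromseq, strand) {
  cds <- tx$cds[order(tx$cds$start), ]
  s <- paste(vapply(seq_len(nrow(cds)), function(i)
    substr(chromseq, cds$start[i], cds$end[i]), ""), collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

oracle_cds_positions <- function(tx) {
  cds <- tx$cds[order(tx$cds$start), ]
  unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
}

# SNV consequence for one transcript by full mutate-and-translate
oracle_snv_category <- function(pos, alt, tx, strand, chromseq) {
  if (pos %in% oracle_splice_sites(tx)) return("splice_essential")
  cds_pos <- if (nrow(tx$cds)) oracle_cds_positions(tx) else integer(0)
  if (pos %in% cds_pos) {
    mutated <- chromseq
    substr(mutated, pos, pos) <- alt
    p0 <- oracle_translate(oracle_extract_cds(tx, chromseq, strand))
    p1 <- oracle_translate(oracle_extract_cds(tx, mutated, strand))
    if (p0 == p1) return("synonymous")
    k <- which(strsplit(p0, "")[[1L]] != strsplit(p1, "")[[1L]])[1L]
    n <- nchar(p0)
    a0 <- substr(p0, k, k); a1 <- substr(p1, k, k)
    if (a0 == "*") return("other")                 # stop-loss
    if (a1 == "*") return(if (k < n) "stopgain" else "other")
    if (k == 1L) return("other")                   # start-loss
    return("missense")
  }
  "noncoding"
}

# transcription-order index of the exon containing pos, and of the last
# CDS-bearing exon
oracle_exon_indices <- function(tx, strand, pos) {
  ex <- tx$exons[order(tx$exons$start), ]
  n <- nrow(ex)
  tr_idx <- function(i) if (strand == "+") i else n - i + 1L
  hit <- which(ex$start <= pos & ex$end >= pos)
  coding <- which(vapply(seq_len(n), function(i)
    any(tx$cds$start <= ex$end[i] & tx$cds$end >= ex$start[i]), logical(1)))
  list(exon = if (length(hit)) tr_idx(hit) else NA_integer_,
       last_coding = if (length(coding)) max(vapply(coding, tr_idx,
                                                    integer(1))) else NA)
}

# conservative-LOF verdict for an SNV (pos, alt) in a gene, from scratch
oracle_snv_lof <- function(pos, alt, gene, chromseq) {
  txs <- gene$transcripts
  splice_all <- all(vapply(txs, function(tx) {
    ss <- oracle_splice_sites(tx)
    length(ss) > 0L && pos %in% ss
  }, logical(1)))
  if (splice_all) return("splice_lof")
  cds_txs <- Filter(function(tx) pos %in% oracle_cds_positions(tx), txs)
  if (length(cds_txs)) {
    ok <- vapply(cds_txs, function(tx) {
      cat_ <- oracle_snv_category(pos, alt, tx, gene$strand, chromseq)
      if (cat_ != "stopgain") return(FALSE)
      idx <- oracle_exon_indices(tx, gene$strand, pos)
      !is.na(idx$exon) && idx$exon != idx$last_coding
    }, logical(1))
    if (all(ok)) return("stopgain_lof")
  }
  "none"
}

# exhaustive potential-LOF count: exonic union + all splice sites x 3 alts
oracle_potential_lof <- function(gene, chromseq) {
  positions <- sort(unique(c(
    unlist(lapply(gene$transcripts, function(tx)
      unlist(lapply(seq_len(nrow(tx$exons)), function(i)
        tx$exons$start[i]:tx$exons$end[i])))),
    unlist(lapply(gene$transcripts, oracle_splice_sites)))))
  n <- 0L
  for (pos in positions) {
    refb <- substr(chromseq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), refb))
      if (oracle_snv_lof(pos, alt, gene, chromseq) != "none") n <- n + 1L
  }
  n
}

# trio decision table (both parents available, diploid autosome)
oracle_trio_mode <- function(p, m, f) {
  stopifnot(p >= 1L)
  if (p == 1L) {
    if (m == 0L && f == 0L) return("de_novo")
    if (m == 2L && f == 2L) return("mendelian_error")
    return("inherited_dominant")
  }
  if (m >= 1L && f >= 1L) return("recessive_homozygous")
  "mendelian_error"
}

oracle_transmission <- function(p, m, f) {
  halves <- function(g) if (g == 0L) 0L else if (g == 2L) 1L else c(0L, 1L)
  if (p %in% outer(halves(m), halves(f), `+`)) "consistent" else "violation"
}
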