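# Variant + genotype ingestion and site-quality filtering.
#
# A variant table is a data.frame with columns chrom, pos (1-based), ref,
# alt, vclass in {SNV, insertion, deletion, MNV}, key. Genotypes are an
# integer matrix (variants x samples) of alt-allele counts, NA = missing.
# Site quality is a data.frame aligned row-wise with the variant table.

classify_vclass <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV",
         ifelse(lr < la & substr(alt, 1L, 1L) == substr(ref, 1L, 1L), "insertion",
                ifelse(lr > la & substr(ref, 1L, 1L) == substr(alt, 1L, 1L),
                       "deletion", "MNV")))
}

# minimal left-trimmed representation: drop shared suffix, then shared prefix
# beyond the anchor base, adjusting pos
normalize_variant <- function(chrom, pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

make_variant_table <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vclass = character(0), key = character(0)))
  norm <- mapply(normalize_variant, chrom, pos, ref, alt, SIMPLIFY = FALSE)
  chrom <- vapply(norm, `[[`, "", "chrom")
  pos <- vapply(norm, function(x) as.integer(x$pos), integer(1))
  ref <- vapply(norm, `[[`, "", "ref")
  alt <- vapply(norm, `[[`, "", "alt")
  stopifnot(all(ref != alt))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = classify_vclass(ref, alt),
             key = variant_key(chrom, pos, ref, alt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a pedigree (PED) file
#'
#' Standard 6-column whitespace-delimited PED: family, individual, father,
#' mother, sex (1 = male, 2 = female), phenotype. `"0"` marks an
#' unavailable parent.
#'
#' @param path PED file path.
#' @return data.frame with columns family_id, sample_id, father_id,
#'   mother_id, sex (`"male"`/`"female"`/NA), phenotype.
#' @export
read_ped <- function(path) {
  p <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("family_id", "sample_id", "father_id",
                                "mother_id", "sex", "phenotype"),
                  colClasses = c(rep("character", 4), "integer", "character"))
  p$sex <- c("male", "female")[match(p$sex, 1:2)]
  p
}

#' Read case variants and genotypes from a VCF
#'
#' Reads a VCF 4.x file via `VariantAnnotation`, decomposes multi-allelic
#' sites into biallelic records, normalizes indel representation, and
#' converts genotypes to alt-allele counts. Site-quality metrics are taken
#' from INFO keys (names configurable).
#'
#' @param path VCF path.
#' @param ped Optional pedigree data.frame from [read_ped()]; sample columns
#'   must all be present in the pedigree when given.
#' @param quality_keys Named character vector mapping SiteQuality fields
#'   (`posterior_prob`, `depth`, `variant_reads`, `allelic_fraction`,
#'   `max_strand_fraction`, `is_homref_call`) to INFO keys.
#' @return List with `variants` (data.frame), `genotypes` (integer matrix,
#'   variants x samples, alt-allele counts, NA missing), and `quality`
#'   (data.frame aligned to `variants`).
#' @export
read_vcf <- function(path, ped = NULL,
                     quality_keys = c(posterior_prob = "PPROB", depth = "TDP",
                                      variant_reads = "VR",
                                      allelic_fraction = "AFRAC",
                                      max_strand_fraction = "MAXSF",
                                      is_homref_call = "HOMREF")) {
  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  samples <- colnames(vcf)
  if (!is.null(ped) && length(samples) &&
      !all(samples %in% ped$sample_id))
    stop("VCF samples absent from pedigree: ",
         paste(setdiff(samples, ped$sample_id), collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alts)
  site_idx <- rep(seq_along(n_alt), n_alt)       # original site per record
  allele_idx <- unlist(lapply(n_alt, seq_len))   # which ALT of that site
  chrom <- as.character(GenomicRanges::seqnames(rr))[site_idx]
  pos <- GenomicRanges::start(rr)[site_idx]
  ref <- as.character(VariantAnnotation::ref(vcf))[site_idx]
  alt <- as.character(unlist(alts))
  variants <- make_variant_table(chrom, pos, ref, alt)

  gt_raw <- if (length(samples)) VariantAnnotation::geno(vcf)$GT else
    matrix(character(0), nrow(vcf), 0L)
  genotypes <- matrix(NA_integer_, nrow(variants), length(samples),
                      dimnames = list(variants$key, samples))
  for (r in seq_len(nrow(variants))) {
    s <- site_idx[r]; a <- as.character(allele_idx[r])
    for (j in seq_along(samples)) {
      g <- gt_raw[s, j]
      al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1L]]
      if (any(al == ".") || !length(al)) next
      genotypes[r, j] <- sum(al == a)
    }
  }

  info <- VariantAnnotation::info(vcf)
  pull <- function(field, default = NA_real_) {
    key <- quality_keys[[field]]
    if (!is.null(key) && key %in% colnames(info)) {
      v <- info[[key]]
      if (is.list(v)) v <- vapply(v, function(x)
        if (length(x)) as.numeric(x[1L]) else NA_real_, numeric(1))
      as.numeric(v)[site_idx]
    } else rep(default, nrow(variants))
  }
  hr_key <- quality_keys[["is_homref_call"]]
  homref <- if (!is.null(hr_key) && hr_key %in% colnames(info))
    as.logical(info[[hr_key]])[site_idx] else rep(FALSE, nrow(variants))
  quality <- data.frame(
    posterior_prob = pull("posterior_prob"),
    depth = pull("depth"),
    variant_reads = pull("variant_reads"),
    allelic_fraction = pull("allelic_fraction"),
    max_strand_fraction = pull("max_strand_fraction"),
    is_homref_call = homref)

  list(variants = variants, genotypes = genotypes, quality = quality)
}

#' Write a variant set to VCF
#'
#' Emits a minimal well-formed VCF 4.2 with GT genotypes and the package's
#' site-quality INFO keys.
#'
#' @param variants Variant data.frame (chrom, pos, ref, alt).
#' @param genotypes Integer matrix of alt-allele counts (variants x
#'   samples), NA = missing; `NULL` for a site-only VCF.
#' @param quality Optional site-quality data.frame aligned to `variants`.
#' @param path Output path.
#' @param ploidy Integer vector per variant (2 default; 1 emits haploid GT).
#' @param hemi Optional logical matrix (same shape as `genotypes`) marking
#'   hemizygous entries to emit as haploid GT regardless of `ploidy`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes = NULL, quality = NULL, path,
                      ploidy = rep(2L, nrow(variants)), hemi = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (chrom in unique(variants$chrom))
    writeLines(sprintf("##contig=<ID=%s>", chrom), con)
  writeLines(c(
    '##INFO=<ID=PPROB,Number=1,Type=Float,Description="Posterior probability">',
    '##INFO=<ID=TDP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=VR,Number=1,Type=Integer,Description="Variant reads">',
    '##INFO=<ID=AFRAC,Number=1,Type=Float,Description="Allelic fraction">',
    '##INFO=<ID=MAXSF,Number=1,Type=Float,Description="Max strand fraction">',
    '##INFO=<ID=HOMREF,Number=0,Type=Flag,Description="Homozygous reference call">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  samples <- if (is.null(genotypes)) character(0) else colnames(genotypes)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", if (length(samples)) c("FORMAT", samples)),
                   collapse = "\t"), con)
  gt_string <- function(count, pl) {
    if (is.na(count)) return(if (pl == 1L) "." else "./.")
    if (pl == 1L) as.character(count)
    else c("0/0", "0/1", "1/1")[count + 1L]
  }
  for (i in seq_len(nrow(variants))) {
    info <- "."
    if (!is.null(quality)) {
      parts <- c(sprintf("PPROB=%g", quality$posterior_prob[i]),
                 sprintf("TDP=%d", as.integer(quality$depth[i])),
                 sprintf("VR=%d", as.integer(quality$variant_reads[i])),
                 sprintf("AFRAC=%g", quality$allelic_fraction[i]),
                 sprintf("MAXSF=%g", quality$max_strand_fraction[i]))
      if (isTRUE(quality$is_homref_call[i])) parts <- c(parts, "HOMREF")
      info <- paste(parts, collapse = ";")
    }
    fields <- c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
                variants$alt[i], ".", "PASS", info)
    if (length(samples)) {
      pls <- rep(ploidy[i], length(samples))
      if (!is.null(hemi)) pls[hemi[i, ]] <- 1L
      fields <- c(fields, "GT",
                  mapply(gt_string, genotypes[i, ], pls))
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

# -- site-quality filters ----------------------------------------------------

#' SNV site-quality filter
#'
#' A site fails if any of: posterior probability < 0.95; total depth < 10;
#' fewer than 3 variant reads; allelic fraction < 10%; >= 99% of reads on a
#' single strand; a homozygous-reference call with < 6x coverage. Missing
#' metrics fail the corresponding rule (reason `missing_metric:<rule>`).
#'
#' @param quality data.frame (or one-row list) with posterior_prob, depth,
#'   variant_reads, allelic_fraction, max_strand_fraction, is_homref_call.
#' @return data.frame with logical `pass` and list-column `fail_reasons`.
#' @export
snv_quality_filter <- function(quality) {
  quality <- as.data.frame(quality)
  n <- nrow(quality)
  reasons <- vector("list", n)
  rule <- function(vals, fails, name) {
    for (i in seq_len(n)) {
      if (is.na(vals[i])) reasons[[i]] <<- c(reasons[[i]],
                                             paste0("missing_metric:", name))
      else if (fails[i]) reasons[[i]] <<- c(reasons[[i]], name)
    }
  }
  rule(quality$posterior_prob, quality$posterior_prob < 0.95, "posterior_prob")
  rule(quality$depth, quality$depth < 10, "depth")
  rule(quality$variant_reads, quality$variant_reads < 3, "variant_reads")
  rule(quality$allelic_fraction, quality$allelic_fraction < 0.10,
       "allelic_fraction")
  rule(quality$max_strand_fraction, quality$max_strand_fraction >= 0.99,
       "strand_bias")
  homref <- quality$is_homref_call
  homref[is.na(homref)] <- FALSE
  rule(quality$depth, homref & quality$depth < 6, "homref_low_coverage")
  out <- data.frame(pass = lengths(reasons) == 0L)
  out$fail_reasons <- reasons
  out
}

#' Indel site-quality filter
#'
#' Applies all SNV rules first, then the stricter indel rules: total depth
#' < 30x or allelic fraction < 30% fail.
#'
#' @inheritParams snv_quality_filter
#' @return data.frame with `pass` and list-column `fail_reasons`.
#' @export
indel_quality_filter <- function(quality) {
  quality <- as.data.frame(quality)
  out <- snv_quality_filter(quality)
  reasons <- out$fail_reasons
  for (i in seq_len(nrow(quality))) {
    r <- reasons[[i]]
    d <- quality$depth[i]; af <- quality$allelic_fraction[i]
    if (is.na(d)) r <- c(r, "missing_metric:indel_depth")
    else if (d < 30) r <- c(r, "indel_depth")
    if (is.na(af)) r <- c(r, "missing_metric:indel_allelic_fraction")
    else if (af < 0.30) r <- c(r, "indel_allelic_fraction")
    reasons[i] <- list(r)   # list-assign: r may be empty
  }
  out$fail_reasons <- reasons
  out$pass <- lengths(reasons) == 0L
  out
}

# -- allele-frequency panels -------------------------------------------------

#' Read a frequency-panel TSV
#'
#' Columns: chrom, pos, ref, alt, panel, alt_count, total_alleles.
#'
#' @param path TSV path.
#' @return data.frame with an added `key` column.
#' @export
read_panels <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  p$key <- variant_key(p$chrom, p$pos, p$ref, p$alt)
  p
}

#' Minor allele frequency of a frequency record
#'
#' @param alt_count Alt allele count(s) in the panel.
#' @param total_alleles Total allele count(s); must be > 0.
#' @return Minor-allele frequency in `[0, 0.5]`.
#' @export
panel_maf <- function(alt_count, total_alleles) {
  if (any(total_alleles == 0))
    stop("undefined frequency: total_alleles is zero")
  pmin(alt_count, total_alleles - alt_count) / total_alleles
}
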