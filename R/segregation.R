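# Inheritance-mode classification from trio genotypes.
#
# Genotypes are alt-allele counts: diploid {0,1,2}, hemizygous {0,1},
# NA = sample unavailable. Parental affected status is not modeled;
# labels are genotype-only, and a de novo call assumes parental genotype
# calls are correct (mosaicism out of scope).

#' Mendelian transmission check for a full trio
#'
#' @param proband,mother,father Diploid alt-allele counts (0/1/2); all
#'   three must be available.
#' @return `"consistent"` or `"violation"`.
#' @export
mendelian_consistency <- function(proband, mother, father) {
  if (any(is.na(c(proband, mother, father))))
    stop("mendelian_consistency requires all three genotypes")
  from <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  possible <- unique(as.vector(outer(from(mother), from(father), `+`)))
  if (proband %in% possible) "consistent" else "violation"
}

#' Classify the inheritance mode of a variant from trio genotypes
#'
#' Modes: `de_novo` (carrier proband, both parents available and
#' non-carrier), `inherited_dominant` (het proband, an available parent
#' carries), `recessive_homozygous` (hom-alt proband, every available
#' parent carries), `x_linked` (male hemizygous proband on X, carrier
#' mother, non-carrier or absent father), `unknown` (exactly one parent
#' available and that parent is non-carrier), `unresolved` (no parent
#' available or otherwise undecidable), `mendelian_error` (impossible
#' transmission, e.g. hom-alt proband with an available non-carrier
#' parent).
#'
#' @param proband Proband alt-allele count (>= 1; diploid 1/2, hemizygous 1).
#' @param mother,father Parental alt-allele counts; `NA` = unavailable.
#' @param chrom_class `"autosome"`, `"X"` or `"Y"`.
#' @param proband_sex `"male"` or `"female"`.
#' @return Mode string.
#' @export
classify_trio <- function(proband, mother, father,
                          chrom_class = "autosome", proband_sex = "female") {
  if (is.na(proband) || proband < 1L)
    stop("classify_trio requires a carrier proband")
  m_av <- !is.na(mother); f_av <- !is.na(father)
  hemi <- chrom_class == "X" && proband_sex == "male"

  if (hemi) {
    # son's X is maternal; father's genotype cannot transmit
    if (m_av && mother >= 1L && (!f_av || father == 0L)) return("x_linked")
    if (m_av && f_av && mother == 0L && father == 0L) return("de_novo")
    if (m_av && mother == 0L && !f_av) return("unknown")
    if (m_av && f_av && mother == 0L) return("de_novo")  # father carrier, X not paternal
    return("unresolved")
  }

  if (!m_av && !f_av) return("unresolved")

  if (m_av && f_av) {
    if (proband == 1L) {
      if (mother == 0L && father == 0L) return("de_novo")
      if (mother == 2L && father == 2L) return("mendelian_error")
      return("inherited_dominant")
    }
    if (proband == 2L) {
      if (mother >= 1L && father >= 1L) return("recessive_homozygous")
      return("mendelian_error")
    }
    return("unresolved")
  }

  # exactly one parent available
  par <- if (m_av) mother else father
  if (proband == 1L) {
    if (par >= 1L) return("inherited_dominant")
    return("unknown")
  }
  if (proband == 2L) {
    if (par >= 1L) return("recessive_homozygous")
    return("mendelian_error")
  }
  "unresolved"
}

#' Classify every candidate call of a cohort against its trio
#'
#' @param calls data.frame with at least `case_id`, `key`, `gene_id`, and
#'   `chrom`.
#' @param genotypes Alt-allele-count matrix (variant keys x samples)
#'   covering probands and any available parents.
#' @param ped Pedigree from [read_ped()]; parent IDs of `"0"` or parents
#'   missing from the genotype matrix count as unavailable.
#' @param x_chroms Chromosome names treated as X (default `c("X","chrX")`).
#' @return `calls` with `mode` and `partner_variant` columns appended
#'   (compound-het partners from [compound_het_scan()]).
#' @export
segregate_calls <- function(calls, genotypes, ped,
                            x_chroms = c("X", "chrX")) {
  gt_of <- function(key, sample) {
    if (is.na(sample) || !sample %in% colnames(genotypes) ||
        !key %in% rownames(genotypes)) return(NA_integer_)
    genotypes[key, sample]
  }
  parent_ids <- function(case_id) {
    i <- match(case_id, ped$sample_id)
    if (is.na(i)) return(c(mother = NA_character_, father = NA_character_))
    m <- ped$mother_id[i]; f <- ped$father_id[i]
    c(mother = if (identical(m, "0")) NA_character_ else m,
      father = if (identical(f, "0")) NA_character_ else f)
  }
  ped$sex <- ifelse(ped$sex %in% c("1", 1L, "male"), "male",
                    ifelse(ped$sex %in% c("2", 2L, "female"), "female",
                           NA_character_))
  calls$mode <- NA_character_
  calls$partner_variant <- NA_character_
  for (i in seq_len(nrow(calls))) {
    case <- calls$case_id[i]
    par <- parent_ids(case)
    sex <- ped$sex[match(case, ped$sample_id)]
    chrom_class <- if (calls$chrom[i] %in% x_chroms) "X" else "autosome"
    pg <- gt_of(calls$key[i], case)
    if (is.na(pg) || pg < 1L) {
      calls$mode[i] <- "unresolved"
      next
    }
    calls$mode[i] <- classify_trio(
      pg, gt_of(calls$key[i], par["mother"]), gt_of(calls$key[i], par["father"]),
      chrom_class = chrom_class,
      proband_sex = if (is.na(sex)) "female" else sex)
  }
  # compound-het pass over het calls per (case, gene)
  ch <- compound_het_scan(calls, genotypes, ped)
  if (nrow(ch)) {
    for (j in seq_len(nrow(ch))) {
      sel <- which(calls$case_id == ch$case_id[j] &
                   calls$key %in% c(ch$variant_a[j], ch$variant_b[j]))
      calls$mode[sel] <- "recessive_compound_het"
      for (s in sel)
        calls$partner_variant[s] <- setdiff(c(ch$variant_a[j], ch$variant_b[j]),
                                            calls$key[s])[1L]
    }
  }
  calls
}

#' Scan for compound heterozygotes in trans
#'
#' For each (case, gene) with two or more heterozygous proband variants
#' and both parents available, emits pairs where one variant is carried by
#' the mother only and the other by the father only (trans configuration
#' established by parental genotypes). Cis pairs (same single parent) and
#' ambiguous pairs (a parentless-origin or double-carrier variant) are not
#' emitted.
#'
#' @param calls data.frame with `case_id`, `gene_id`, `key`.
#' @param genotypes Alt-allele-count matrix (keys x samples).
#' @param ped Pedigree from [read_ped()].
#' @return data.frame (case_id, gene_id, variant_a, variant_b), zero rows
#'   when no trans pair exists.
#' @export
compound_het_scan <- function(calls, genotypes, ped) {
  out <- list()
  for (grp in split(calls, paste(calls$case_id, calls$gene_id, sep = "\r"))) {
    if (nrow(grp) < 2L) next
    case <- grp$case_id[1L]
    i <- match(case, ped$sample_id)
    if (is.na(i)) next
    m <- ped$mother_id[i]; f <- ped$father_id[i]
    if (identical(m, "0") || identical(f, "0") ||
        !m %in% colnames(genotypes) || !f %in% colnames(genotypes)) next
    origin <- vapply(grp$key, function(k) {
      if (!k %in% rownames(genotypes)) return("ambiguous")
      pg <- genotypes[k, case]
      if (is.na(pg) || pg != 1L) return("ambiguous")
      mg <- genotypes[k, m]; fg <- genotypes[k, f]
      if (is.na(mg) || is.na(fg)) return("ambiguous")
      if (mg >= 1L && fg == 0L) "maternal"
      else if (fg >= 1L && mg == 0L) "paternal"
      else "ambiguous"
    }, "")
    mat <- grp$key[origin == "maternal"]
    pat <- grp$key[origin == "paternal"]
    for (a in mat) for (b in pat)
      out[[length(out) + 1L]] <- data.frame(case_id = case,
                                            gene_id = grp$gene_id[1L],
                                            variant_a = a, variant_b = b)
  }
  if (!length(out))
    return(data.frame(case_id = character(0), gene_id = character(0),
                      variant_a = character(0), variant_b = character(0)))
  do.call(rbind, out)
}
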