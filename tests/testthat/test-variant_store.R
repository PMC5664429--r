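quality_row <- function(posterior_prob = 0.99, depth = 50, variant_reads = 25,
                        allelic_fraction = 0.5, max_strand_fraction = 0.55,
                        is_homref_call = FALSE) {
  data.frame(posterior_prob = posterior_prob, depth = depth,
             variant_reads = variant_reads,
             allelic_fraction = allelic_fraction,
             max_strand_fraction = max_strand_fraction,
             is_homref_call = is_homref_call)
}

test_that("SNV filter thresholds behave at their boundaries", {
  # all thresholds exactly met -> pass
  q <- quality_row(0.95, 10, 3, 0.10, 0.98, FALSE)
  r <- snv_quality_filter(q)
  expect_true(r$pass)
  expect_length(r$fail_reasons[[1L]], 0L)
  # depth 9 alone fails with the depth reason
  r <- snv_quality_filter(quality_row(depth = 9))
  expect_false(r$pass)
  expect_identical(r$fail_reasons[[1L]], "depth")
  # 99% single-strand reads is flagged (inclusive)
  expect_false(snv_quality_filter(quality_row(max_strand_fraction = 0.99))$pass)
  # homref call below 6x
  expect_false(snv_quality_filter(
    quality_row(depth = 5, is_homref_call = TRUE))$pass)
  # missing metric fails that rule
  r <- snv_quality_filter(quality_row(posterior_prob = NA))
  expect_false(r$pass)
  expect_true("missing_metric:posterior_prob" %in% r$fail_reasons[[1L]])
})

test_that("indel filter applies SNV rules plus the stricter indel rules", {
  expect_false(indel_quality_filter(
    quality_row(depth = 29, allelic_fraction = 0.5))$pass)
  expect_true(indel_quality_filter(
    quality_row(depth = 30, allelic_fraction = 0.30))$pass)
  expect_false(indel_quality_filter(
    quality_row(depth = 100, allelic_fraction = 0.29))$pass)
})

test_that("filters match an independent predicate oracle on random draws", {
  set.seed(42)
  n <- 1000L
  q <- data.frame(
    posterior_prob = round(runif(n, 0.90, 1.0), 3),
    depth = sample(0:60, n, replace = TRUE),
    variant_reads = sample(0:20, n, replace = TRUE),
    allelic_fraction = round(runif(n, 0, 0.6), 3),
    max_strand_fraction = round(runif(n, 0.5, 1.0), 3),
    is_homref_call = sample(c(TRUE, FALSE), n, replace = TRUE))
  q$variant_reads <- pmin(q$variant_reads, q$depth)
  snv_oracle <- with(q, !(posterior_prob < 0.95 | depth < 10 |
                          variant_reads < 3 | allelic_fraction < 0.10 |
                          max_strand_fraction >= 0.99 |
                          (is_homref_call & depth < 6)))
  indel_oracle <- snv_oracle & with(q, !(depth < 30 |
                                         allelic_fraction < 0.30))
  got_snv <- snv_quality_filter(q)
  got_indel <- indel_quality_filter(q)
  expect_identical(got_snv$pass, unname(snv_oracle))
  expect_identical(got_indel$pass, unname(indel_oracle))
  # pass <=> no fail reasons
  expect_identical(got_snv$pass, lengths(got_snv$fail_reasons) == 0L)
  expect_identical(got_indel$pass, lengths(got_indel$fail_reasons) == 0L)
})

test_that("panel_maf folds to the minor allele", {
  expect_equal(panel_maf(5L, 1000L), 0.005)
  expect_equal(panel_maf(998L, 1000L), 0.002)
  expect_error(panel_maf(0L, 0L), "total_alleles")
  set.seed(7)
  ac <- sample(0:500, 200, replace = TRUE)
  tot <- ac + sample(0:500, 200, replace = TRUE) + 1L
  expect_equal(panel_maf(ac, tot), pmin(ac / tot, 1 - ac / tot))
})

test_that("read_vcf parses a trio VCF and decomposes multi-allelic sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "M1", "F1", sep = "\t"))
  body <- c(
    vapply(1:9, function(i)
      paste("chr1", 100L + 10L * i, ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "0/0", "0/1", sep = "\t"), ""),
    paste("chr1", 500L, ".", "A", "C,T", ".", "PASS", ".", "GT",
          "1/2", "0/1", "0/2", sep = "\t"))
  writeLines(c(header, body), path)
  v <- read_vcf(path)
  # 9 biallelic + 2 decomposed records
  expect_equal(nrow(v$variants), 11L)
  expect_equal(sum(v$variants$pos == 500L), 2L)
  expect_setequal(v$variants$alt[v$variants$pos == 500L], c("C", "T"))
  expect_equal(dim(v$genotypes), c(11L, 3L))
  # decomposition preserves per-sample alt counts
  kC <- "chr1:500:A:C"; kT <- "chr1:500:A:T"
  expect_equal(unname(v$genotypes[kC, ]), c(1L, 1L, 0L))
  expect_equal(unname(v$genotypes[kT, ]), c(1L, 0L, 1L))
})

test_that("read_vcf rejects samples missing from the pedigree", {
  sim <- shared_sim()
  dir <- withr::local_tempdir()
  spec <- sim$spec
  trios <- simulate_trios(spec, sim$genome,
                          modes = c(de_novo = 2L, inherited_dominant = 2L))
  paths <- write_trio_data(trios, dir)
  ped <- read_ped(paths[["ped"]])
  expect_silent(read_vcf(paths[["trio_vcf"]], ped = ped))
  ped_bad <- ped[-1L, ]
  expect_error(read_vcf(paths[["trio_vcf"]], ped = ped_bad),
               "absent from pedigree")
})

test_that("write_vcf then read_vcf round-trips variants and genotypes", {
  sim <- shared_sim()
  planted <- sim$planted
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(planted$variants, planted$genotypes, planted$quality, path)
  back <- read_vcf(path)
  ord <- match(planted$variants$key, back$variants$key)
  expect_false(any(is.na(ord)))
  expect_equal(back$variants[ord, c("chrom", "pos", "ref", "alt", "vclass")],
               planted$variants[, c("chrom", "pos", "ref", "alt", "vclass")],
               ignore_attr = TRUE)
  expect_equal(unname(back$genotypes[ord, colnames(planted$genotypes)]),
               unname(planted$genotypes))
  expect_equal(back$quality$depth[ord], planted$quality$depth)
  expect_equal(back$quality$posterior_prob[ord],
               planted$quality$posterior_prob)
})
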