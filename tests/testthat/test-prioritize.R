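panel_fixture <- function(key, internal_ac = NA, internal_tot = 10984L,
                          public_maf = 0) {
  parts <- strsplit(key, ":")[[1L]]
  base <- data.frame(chrom = parts[1L], pos = as.integer(parts[2L]),
                     ref = parts[3L], alt = parts[4L])
  rows <- list()
  if (!is.na(internal_ac))
    rows[[1L]] <- cbind(base, panel = "internal", alt_count = internal_ac,
                        total_alleles = internal_tot)
  rows[[length(rows) + 1L]] <-
    cbind(base, panel = "ExAC",
          alt_count = as.integer(round(public_maf * 100000L)),
          total_alleles = 100000L)
  p <- do.call(rbind, rows)
  p$key <- key
  p
}

test_that("rarity tiers follow the internal and public MAF thresholds", {
  k <- "chr1:100:A:T"
  # absent internally, public below 0.5% -> case-exclusive
  t <- rarity_tier(k, panel_fixture(k, internal_ac = NA,
                                    public_maf = 0.004))
  expect_equal(t$tier, "case_exclusive")
  expect_true(t$internal_absent)
  # internal MAF 0.06% fails the < 0.05% rule -> common
  t <- rarity_tier(k, panel_fixture(k, internal_ac = 7L,
                                    internal_tot = 11000L))
  expect_equal(t$tier, "common")
  # internal MAF just under 0.05% -> rare
  t <- rarity_tier(k, panel_fixture(k, internal_ac = 2L))
  expect_equal(t$tier, "rare")
  # public panel at or above 0.5% demotes even internally-absent variants
  t <- rarity_tier(k, panel_fixture(k, internal_ac = NA, public_maf = 0.01))
  expect_equal(t$tier, "common")
  # no panel records at all -> frequency zero everywhere -> case-exclusive
  empty <- panel_fixture(k)[0, ]
  expect_equal(rarity_tier(k, empty)$tier, "case_exclusive")
})

test_that("rarity tiers match a direct predicate oracle on random tables", {
  set.seed(31)
  for (r in 1:200) {
    k <- sprintf("chr1:%d:A:T", r)
    iac <- sample(c(NA, 0L, 1L, 2L, 5L, 10L, 60L), 1L)
    pmaf <- sample(c(0, 1e-4, 4e-3, 6e-3, 2e-2), 1L)
    p <- panel_fixture(k, internal_ac = iac, public_maf = pmaf)
    got <- rarity_tier(k, p)$tier
    i_ac <- if (is.na(iac)) 0L else iac
    i_maf <- if (i_ac == 0L) 0 else min(i_ac, 10984L - i_ac) / 10984L
    want <- if (i_ac == 0L && pmaf < 0.005) "case_exclusive"
      else if (i_maf < 0.0005 && pmaf < 0.005) "rare" else "common"
    expect_identical(got, want, info = paste(iac, pmaf))
  }
})

test_that("tightening MAF thresholds never grows the retained set", {
  sim <- shared_sim()
  panels <- sim$planted$panels
  keys <- sim$planted$variants$key
  loose <- rarity_tier(keys, panels)
  tight <- rarity_tier(keys, panels, public_maf = 0.001,
                       internal_maf = 0.0001)
  kept <- function(t) t$key[t$tier != "common"]
  expect_true(all(kept(tight) %in% kept(loose)))
})

test_that("recurrent LOF sites are pruned above two case observations", {
  keys <- paste0("chr1:", 1:3, ":A:T")
  gt <- matrix(0L, 3L, 6L, dimnames = list(keys, paste0("c", 1:6)))
  gt[1L, 1:3] <- 1L           # seen three times -> pruned
  gt[2L, 1:2] <- c(1L, 2L)    # two carrier cases -> retained
  gt[3L, 1:4] <- 1L           # DNS: untouched regardless
  calls <- data.frame(key = keys,
                      lof_class = c("stopgain_lof", "splice_lof", "none"))
  out <- recurrence_prune(calls, gt)
  expect_setequal(out$key, keys[2:3])
  expect_equal(attr(out, "removed"), keys[1L])
  # occurrence counting counts carriers, so a hom case is one observation
  gt[2L, 3L] <- 2L            # third carrier -> now pruned
  expect_false(keys[2L] %in% recurrence_prune(calls, gt)$key)
})

test_that("a-priori intersection keeps listed genes and attaches sources", {
  apriori <- data.frame(gene = c("AAA", "BBB"),
                        sources = c("MGI,TGFB", "CVM"))
  calls <- data.frame(key = paste0("k", 1:3),
                      symbol = c("AAA", "CCC", "BBB"))
  out <- apriori_intersect(calls, apriori)
  expect_equal(out$symbol, c("AAA", "BBB"))
  expect_equal(out$apriori_sources, c("MGI,TGFB", "CVM"))
  expect_error(apriori_intersect(calls, apriori[0, ]), "empty")
})

test_that("working-gene expansion emits rare DNS in de novo LOF genes only", {
  ann <- data.frame(key = paste0("k", 1:4),
                    symbol = c("G1", "G1", "G2", "G3"),
                    dns = c(TRUE, FALSE, TRUE, TRUE))
  tiers <- data.frame(key = paste0("k", 1:4),
                      tier = c("rare", "rare", "case_exclusive", "common"))
  out <- working_gene_expansion(c("G1", "G2", "G3"), ann, tiers)
  expect_setequal(out$key, c("k1", "k3"))   # k2 not DNS, k4 too common
  expect_true(all(out$expansion))
  expect_equal(nrow(working_gene_expansion(character(0), ann, tiers)), 0L)
})

test_that("known-pathogenic cross-reference tiers on the internal panel", {
  keys <- sprintf("chr1:%d:A:T", 1:4)
  patho <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
                      source = "ClinVar")
  patho$key <- keys
  panels <- rbind(panel_fixture(keys[2L], internal_ac = 2L),
                  panel_fixture(keys[3L], internal_ac = 110L),
                  panel_fixture(keys[4L], internal_ac = 600L))
  out <- known_pathogenic_crossref(keys[1:3], patho, panels)
  expect_equal(out$tier[out$key == keys[1L]], "case_exclusive_reported")
  expect_equal(out$tier[out$key == keys[2L]], "mac_lt_5")
  expect_equal(out$tier[out$key == keys[3L]], "high_freq_deprioritized")
  # unmatched case keys and unobserved pathogenic rows are not reported
  expect_false(keys[4L] %in% out$key)
  counts <- attr(out, "tier_counts")
  expect_equal(as.integer(counts[c("case_exclusive_reported", "mac_lt_5",
                                   "high_freq_deprioritized")]),
               c(1L, 1L, 1L))
})

test_that("the funnel is monotone and deterministic on planted data", {
  sim <- shared_sim()
  dir <- withr::local_tempdir()
  paths <- c(write_genome(sim$genome, dir),
             write_case_data(sim$planted, dir))
  config <- list(gtf = paths[["gtf"]], fasta = paths[["fasta"]],
                 case_vcf = paths[["case_vcf"]],
                 panels = paths[["panels"]],
                 predictors = paths[["predictors"]],
                 apriori = paths[["apriori"]])
  rep1 <- run_discovery_pipeline(config, verbose = FALSE)
  # each funnel stage only narrows the LOF candidate set
  expect_true(all(rep1$stages$recurrence %in% rep1$stages$lof_rarity))
  expect_true(all(rep1$stages$constraint_gate %in% rep1$stages$recurrence))
  expect_true(all(rep1$stages$apriori %in% rep1$stages$constraint_gate))
  # deterministic re-run
  rep2 <- run_discovery_pipeline(config, verbose = FALSE)
  expect_identical(rep1$candidates, rep2$candidates)
  expect_identical(rep1$summary, rep2$summary)
  # survivors equal the generator's funnel expectation exactly
  truth <- sim$planted$truth
  expect_setequal(unique(rep1$candidates$key),
                  truth$key[truth$funnel_expected])
})
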