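test_that("site statistics follow the dosage-weighted definitions", {
  gm <- gm_from_cols(list(c(0L, 2L, 2L, 2L)))
  st <- site_stats(gm)
  expect_equal(st$maf, 0.25)  # f = 0.75
  st2 <- site_stats(gm_from_cols(list(c(1L, 1L))))
  expect_equal(st2$het_fraction, 1.0)
  expect_equal(st2$maf, 0.5)
  gm3 <- gm_from_cols(list(c(rep(0L, 6), rep(NA_integer_, 4))))
  expect_equal(site_stats(gm3)$missing_fraction, 0.4)
})

test_that("site filters remove planted violations with per-reason counts", {
  set.seed(31)
  n <- 40
  good <- replicate(20, sample(c(0L, 2L), n, TRUE), simplify = FALSE)
  low_maf <- replicate(3, c(2L, rep(0L, n - 1)), simplify = FALSE)   # maf 1/80
  high_miss <- replicate(4, c(sample(c(0L, 2L), n - 15, TRUE),
                              rep(NA_integer_, 15)), simplify = FALSE)
  high_het <- replicate(2, c(rep(1L, 5), sample(c(0L, 2L), n - 5, TRUE)),
                        simplify = FALSE)
  gm <- gm_from_cols(c(good, low_maf, high_miss, high_het))
  res <- filter_sites(gm, maf_min = 0.05, missing_max = 0.20, het_max = 0.05)
  expect_equal(unname(res$log$counts["maf"]), 3)
  expect_equal(unname(res$log$counts["missing"]), 4)
  expect_equal(unname(res$log$counts["het"]), 2)
  expect_equal(n_sites(res$geno), 20)
  expect_setequal(res$geno$sites$id,
                  oracle_filter_sites(gm, 0.05, 0.20, 0.05))
})

test_that("allelic tag test flags only significant excess het/missing", {
  # ideal allelic site: no hets, no missing -> OR = 0, never flagged
  ideal <- gm_from_cols(list(c(rep(0L, 50), rep(2L, 50))))
  t1 <- allelic_tag_test(ideal)
  expect_equal(t1$odds_ratio, 0)
  expect_false(t1$flagged)

  # paralog-like: 30 het / 5 / 5 / 30 missing
  par_gm <- gm_from_cols(list(c(rep(1L, 30), rep(0L, 5), rep(2L, 5),
                                rep(NA_integer_, 30))))
  t2 <- allelic_tag_test(par_gm)
  expect_equal(t2$p_value, oracle_fisher_p(30, 5, 5, 30), tolerance = 1e-12)
  expect_true(t2$flagged)

  # weak association never survives Bonferroni at alpha 0.001
  weak <- gm_from_cols(list(c(1L, rep(0L, 49), rep(2L, 49), NA_integer_)))
  t3 <- allelic_tag_test(weak)
  expect_equal(t3$p_value, oracle_fisher_p(1, 49, 49, 1), tolerance = 1e-12)
  expect_false(t3$flagged)
  expect_error(allelic_tag_test(ideal, alpha = 1.5), "alpha")
})

test_that("exact-test p-values agree with fisher.test on random tables", {
  set.seed(41)
  for (rep in 1:100) {
    tab <- as.integer(sample(0:20, 4, replace = TRUE))
    if (sum(tab) < 2) next
    p_pkg <- lineagescope:::.fisher_p2(tab[1], tab[2], tab[3], tab[4])
    p_ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("sample filters remove on either threshold with exact sets", {
  set.seed(51)
  calls <- matrix(sample(c(0L, 2L), 20 * 100, TRUE), 20, 100)
  calls[1, 1:85] <- NA_integer_          # 85% missing
  calls[2, 1:10] <- 1L                   # 10% het
  rownames(calls) <- sprintf("X%03d", 1:20)
  gm <- genotype_matrix(calls, data.frame(id = sprintf("s%03d", 1:100),
                                          chrom = "c1", pos = 1:100,
                                          ref = "A", alt = "G"))
  res <- filter_samples(gm)
  expect_setequal(res$log$id, c("X001", "X002"))
  expect_setequal(res$log$id, oracle_filter_samples(gm, 0.80, 0.05))
  expect_equal(n_samples(res$geno), 18)
  # a matrix of only failing samples cannot survive
  expect_error(filter_samples(gm[c("X001", "X002"), ]), "all samples removed")
})

test_that("group-private site removal matches the exhaustive oracle", {
  gm <- gm_from_cols(list(c(0L, 0L, 0L, 2L, 2L),    # segregates only in grp
                          c(0L, 2L, 0L, 0L, 0L),    # segregates only outside
                          c(0L, 2L, 0L, 2L, 0L)))   # segregates in both
  part <- setNames(c("a", "a", "a", "w", "w"), sample_ids(gm))
  res <- drop_group_private_sites(gm, part, "w")
  expect_equal(res$removed, "s01")
  expect_equal(res$count, 1L)

  set.seed(61)
  for (rep in 1:20) {
    g <- random_gm(20, 50, missing = 0.15)
    in_grp <- seq_len(20) %in% sample(20, 6)
    part <- setNames(ifelse(in_grp, "w", "t"), sample_ids(g))
    res <- drop_group_private_sites(g, part, "w")
    expect_setequal(res$removed, oracle_drop_private(g, in_grp))
  }
  expect_error(drop_group_private_sites(gm, part, "nope"), "unknown group")
})

test_that("the QC cascade is idempotent once no samples are removed", {
  # the planted F1 is (correctly) removed by the heterozygosity sample
  # filter, which shifts site statistics; on a panel without sample-level
  # removals the cascade is a fixed point
  sim <- simulate_panel(sim_config(n_f1 = 0, seed = 5))
  part <- as_partition(sim$passport)
  r1 <- qc_pipeline(sim$geno, part, private_group = "wheat")
  expect_equal(nrow(r1$log$sample_filter), 0L)
  r2 <- qc_pipeline(r1$geno, part, private_group = "wheat")
  expect_identical(r2$geno$calls, r1$geno$calls)
  expect_identical(dim(r1$geno$calls), r1$log$output)
})
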