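test_that("partial correlation reduces, saturates and matches the recursive formula", {
  set.seed(2)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  # no covariates: plain correlation
  expect_equal(partial_correlation(x, y, NULL), cor(x, y))
  expect_equal(partial_correlation(x, y, matrix(numeric(0), 50, 0)),
               cor(x, y))
  # y = x exactly: unity for any covariate
  z <- rnorm(50)
  expect_equal(partial_correlation(x, x, cbind(z)), 1, tolerance = 1e-10)

  # 8-point worked dataset, one covariate, against the textbook recursive
  # partial-correlation formula
  x8 <- c(12, 9, 14, 8, 11, 15, 7, 10)
  z8 <- c(3, 2, 5, 1, 4, 6, 1, 3)
  y8 <- c(20, 14, 26, 12, 19, 29, 11, 17)
  expect_equal(partial_correlation(x8, y8, cbind(z8)),
               recursive_partial_cor(x8, y8, z8), tolerance = 1e-12)

  # collinear covariates dropped with a warning, result unchanged
  expect_warning(r2 <- partial_correlation(x, y, cbind(z, 2 * z)),
                 "collinear")
  expect_equal(r2, partial_correlation(x, y, cbind(z)))
  expect_error(partial_correlation(x[1:3], y[1:3], cbind(z[1:3], x[1:3])),
               "at least")
})

test_that("pair covariates difference A minus B and exempt age", {
  pairs <- trait_pairs(n_mz = 12, n_dz = 0, seed = 3)
  # focal phenotype vividness: controls exclude vividness itself
  expect_false("vividness" %in% control_factors("vividness"))
  expect_true("error" %in% control_factors("update"))
  expect_false("memory" %in% control_factors("prior"))
  expect_true("memory" %in% control_factors("update"))

  Z0 <- build_pair_covariates(pairs, "vividness", covariates = "vividness",
                              assignment = rep(FALSE, 12))
  expect_equal(Z0[, "diff_vividness"],
               pairs$vividness_mean_1 - pairs$vividness_mean_2)
  # swapping the assignment flips every difference, age unchanged
  Z1 <- build_pair_covariates(pairs, "vividness", covariates = "vividness",
                              assignment = rep(TRUE, 12))
  expect_equal(Z1[, "diff_vividness"], -Z0[, "diff_vividness"])
  expect_equal(Z1[, "age"], Z0[, "age"])
  # identical factor means within a pair give a zero covariate
  pairs$vividness_mean_2 <- pairs$vividness_mean_1
  Zeq <- build_pair_covariates(pairs, "vividness", covariates = "vividness",
                               assignment = rep(FALSE, 12))
  expect_true(all(Zeq[, "diff_vividness"] == 0))
})

test_that("identical twins give unit permuted correlations", {
  pairs <- trait_pairs(n_mz = 15, n_dz = 0, var_a = 1, var_e = 1e-6, seed = 6)
  pairs$vividness_mean_2 <- pairs$vividness_mean_1
  res <- permutation_twin_correlation(pairs, "vividness",
                                      covariates = character(0),
                                      include_age = FALSE, n_perm = 200,
                                      seed = 1)
  expect_true(all(abs(res$MZ$r - 1) < 1e-12))
})

test_that("monte-carlo permutation agrees with exhaustive reassignment and the ANOVA ICC", {
  pairs <- trait_pairs(n_mz = 10, n_dz = 0, var_a = 0.5, var_e = 0.5,
                       seed = 14)
  ex <- permutation_twin_correlation(pairs, "vividness",
                                     covariates = character(0),
                                     include_age = FALSE, exhaustive = TRUE,
                                     seed = 1)
  expect_equal(ex$MZ$n_perm, 1024)
  mc <- permutation_twin_correlation(pairs, "vividness",
                                     covariates = character(0),
                                     include_age = FALSE, n_perm = 10000,
                                     seed = 2)
  expect_lt(abs(ex$MZ$mean_r - mc$MZ$mean_r), 0.01)

  # larger cohort: mean permuted r converges to the ANOVA intraclass
  # correlation on the same pairs
  big <- trait_pairs(n_mz = 500, n_dz = 0, var_a = 0.4, var_c = 0.2,
                     var_e = 0.4, seed = 15)
  res <- permutation_twin_correlation(big, "vividness",
                                      covariates = character(0),
                                      include_age = FALSE, n_perm = 2000,
                                      seed = 3)
  icc <- anova_icc(big$vividness_mean_1, big$vividness_mean_2)
  expect_lt(abs(res$MZ$mean_r - icc), 0.02)
})

test_that("permutation summaries are seed-stable and ordered", {
  pairs <- trait_pairs(n_mz = 184, n_dz = 80, var_a = 0.4, var_e = 0.6,
                       seed = 25)
  r1 <- permutation_twin_correlation(pairs, "vividness",
                                     covariates = character(0),
                                     include_age = FALSE, n_perm = 10000,
                                     seed = 101)
  r2 <- permutation_twin_correlation(pairs, "vividness",
                                     covariates = character(0),
                                     include_age = FALSE, n_perm = 10000,
                                     seed = 202)
  for (z in c("MZ", "DZ")) {
    expect_lt(abs(r1[[z]]$mean_r - r2[[z]]$mean_r), 0.005)
    expect_lte(r1[[z]]$q2.5, r1[[z]]$mean_r)
    expect_lte(r1[[z]]$mean_r, r1[[z]]$q97.5)
    expect_true(all(abs(r1[[z]]$r) <= 1))
  }
  # AE world with var_a = 0.4: MZ similarity exceeds DZ and tracks var_a
  expect_gt(r1$MZ$mean_r, r1$DZ$mean_r)
  expect_lt(abs(r1$MZ$mean_r - 0.4), 0.12)

  # error names the zygosity when too few pairs remain
  small <- pairs[c(1:5, 185:200), ]
  expect_error(permutation_twin_correlation(small, "vividness",
                                            covariates = character(0),
                                            include_age = FALSE,
                                            n_perm = 10),
               "MZ")
})

test_that("interval overlap verdicts match the study logic", {
  # update row values: MZ [0.30, 0.34] vs DZ [0.03, 0.16] do not overlap
  v <- interval_overlap(c(0.30, 0.34), c(0.03, 0.16))
  expect_false(v$overlap)
  expect_equal(v$larger, "MZ")
  # learning row values
  v2 <- interval_overlap(c(0.25, 0.28), c(0.13, 0.22))
  expect_false(v2$overlap)
  # identical intervals overlap
  expect_true(interval_overlap(c(0.1, 0.3), c(0.1, 0.3))$overlap)
  expect_true(interval_overlap(c(0.1, 0.3), c(0.3, 0.5))$overlap)
})
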