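test_that("the pair likelihood matches the explicit bivariate-normal formula", {
  # single MZ pair, values (1.0, 0.5), mu = 0, sigma2_a = 0.5, sigma2_e = 0.5:
  # Sigma = [[1, 0.5], [0.5, 1]], det = 0.75,
  # quadratic form = (1 - 2*0.5*0.5 + 0.25) / 0.75 = 1
  hand <- -log(2 * pi) - 0.5 * log(0.75) - 0.5 * 1
  expect_equal(pair_loglikelihood(1.0, 0.5, "MZ", sigma2_a = 0.5,
                                  sigma2_e = 0.5), hand)

  # no cross-twin components: factorizes into two univariate normals
  ll <- pair_loglikelihood(1.2, -0.3, "DZ", sigma2_a = 0, sigma2_c = 0,
                           sigma2_e = 2)
  expect_equal(ll, dnorm(1.2, 0, sqrt(2), log = TRUE) +
                 dnorm(-0.3, 0, sqrt(2), log = TRUE))

  # ADE family: DZ off-diagonal is a/2 + d/4
  ll_ade <- pair_loglikelihood(0.4, 0.1, "DZ", sigma2_a = 0.4, sigma2_d = 0.2,
                               sigma2_e = 0.4, family = "ADE")
  s <- 1; o <- 0.5 * 0.4 + 0.25 * 0.2; det <- s^2 - o^2
  qf <- (s * 0.16 - 2 * o * 0.04 + s * 0.01) / det
  expect_equal(ll_ade, -log(2 * pi) - 0.5 * log(det) - 0.5 * qf)

  # singular covariance: -Inf with a flag
  bad <- pair_loglikelihood(1, 1, "MZ", sigma2_a = 1, sigma2_e = 0)
  expect_identical(bad[1], -Inf)
  expect_true(attr(bad, "not_pd"))
  expect_error(pair_loglikelihood(1, 1, "MZ", sigma2_a = -1, sigma2_e = 1),
               "nonnegative")
})

test_that("optimizer deviance matches exhaustive grid search on a small cohort", {
  pairs <- trait_pairs(n_mz = 15, n_dz = 15, var_a = 0.4, var_c = 0.2,
                       var_e = 0.4, seed = 55)
  fit <- fit_biometric(pairs, "vividness", model = "ACE", seed = 1)
  oracle <- grid_deviance_min(pairs, res = 0.02)
  expect_lt(abs(fit$minus2LL - oracle), 0.2)
  expect_lte(fit$minus2LL, oracle + 1e-6)  # optimizer at least as good
})

test_that("fit bookkeeping follows the ep/df/AIC conventions", {
  pairs <- trait_pairs(seed = 8)
  eps <- c(ACE = 4L, ADE = 4L, AE = 3L, CE = 3L, E = 2L)
  for (m in names(eps)) {
    f <- fit_biometric(pairs, "vividness", model = m, seed = 1)
    expect_identical(f$ep, eps[[m]])
    expect_identical(f$df, f$n_subjects - f$ep)
    expect_equal(f$aic, f$minus2LL + 2 * f$ep)
    comps <- sum(f$standardized)
    expect_equal(comps, 100, tolerance = 1e-6)
    expect_true(all(f$standardized >= 0 & f$standardized <= 100))
  }
  expect_error(fit_biometric(pairs, "vividness", model = "DE"),
               "dominance")
})

test_that("richer nested models never fit worse", {
  for (seed in c(3, 17, 29)) {
    pairs <- trait_pairs(n_mz = 60, n_dz = 40, var_a = 0.3, var_c = 0.2,
                         var_e = 0.5, seed = seed)
    d <- sapply(c("ACE", "AE", "CE", "E"), function(m)
      fit_biometric(pairs, "vividness", model = m, seed = 1)$minus2LL)
    tol <- 1e-4
    expect_lte(d["ACE"], d["AE"] + tol)
    expect_lte(d["ACE"], d["CE"] + tol)
    expect_lte(d["AE"], d["E"] + tol)
    expect_lte(d["CE"], d["E"] + tol)
  }
})

test_that("parameter recovery at large n and Falconer agreement", {
  pairs <- trait_pairs(n_mz = 5000, n_dz = 5000, var_a = 0.4, var_e = 0.6,
                       seed = 77)
  fit <- fit_biometric(pairs, "vividness", model = "AE", seed = 1)
  expect_lt(abs(fit$standardized["A"] - 40), 3)
  falc <- falconer_estimate(pairs, "vividness")
  expect_lt(abs(fit$standardized[["A"]] - falc$a_hat_pct), 8)
})

test_that("profile intervals bracket the estimate and hit boundaries", {
  pairs <- trait_pairs(n_mz = 300, n_dz = 150, var_a = 0.4, var_e = 0.6,
                       seed = 91)
  fit <- fit_biometric(pairs, "vividness", model = "AE", seed = 1)
  ci <- profile_ci(fit)
  a <- ci[ci$component == "A", ]
  expect_lt(a$lower, a$estimate)
  expect_gt(a$upper, a$estimate)
  e <- ci[ci$component == "E", ]
  # A and E shares are complementary in a two-component model
  expect_equal(a$lower + e$upper, 100, tolerance = 0.5)

  # E-only model: interval degenerate at 100%
  fe <- fit_biometric(pairs, "vividness", model = "E", seed = 1)
  ce <- profile_ci(fe)
  expect_equal(ce$lower, 100)
  expect_equal(ce$upper, 100)

  # A = 0 world: the AE lower bound collapses onto the zero boundary
  pairs0 <- trait_pairs(n_mz = 150, n_dz = 150, var_a = 0, var_c = 0,
                        var_e = 1, seed = 92)
  fit0 <- fit_biometric(pairs0, "vividness", model = "AE", seed = 1)
  ci0 <- profile_ci(fit0, "A")
  expect_equal(ci0$lower, 0)
  expect_true(ci0$boundary_lower)
})

test_that("AIC selection recovers the generating world", {
  # E world at large n
  pairs_e <- trait_pairs(n_mz = 400, n_dz = 300, var_a = 0, var_c = 0,
                         var_e = 1, seed = 61)
  sel_e <- model_selection(pairs_e, "vividness",
                           models = c("ACE", "AE", "CE", "E"), seed = 1)
  expect_equal(sel_e$winner, "E")
  # C world at large n
  pairs_c <- trait_pairs(n_mz = 400, n_dz = 300, var_a = 0, var_c = 0.5,
                         var_e = 0.5, seed = 62)
  sel_c <- model_selection(pairs_c, "vividness",
                           models = c("ACE", "AE", "CE", "E"), seed = 1)
  expect_equal(sel_c$winner, "CE")
  # table sorted ascending by AIC, winner first
  expect_true(!is.unsorted(sel_c$table$AIC))
  expect_true(sel_c$table$winner[1])
})

test_that("stratified fits recompute phenotypes per event subset", {
  study <- simulate_twin_study(twin_sim_config(n_mz_pairs = 60,
                                               n_dz_pairs = 30, seed = 44))
  subsets <- list(genetic = 1:20, nongenetic = 21:40)
  fits <- stratified_fit(study$trials, subsets, "prior", model = "AE")
  expect_named(fits, c("genetic", "nongenetic"))
  expect_s3_class(fits$genetic, "biometric_fit")
  # identical subsets give identical fits
  twice <- stratified_fit(study$trials, list(a = 1:20, b = 1:20), "prior",
                          model = "AE")
  expect_equal(twice$a$standardized, twice$b$standardized)
  expect_equal(twice$a$minus2LL, twice$b$minus2LL)
  expect_warning(stratified_fit(study$trials, list(tiny = 1:3), "prior"),
                 "fewer than 5")
})
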