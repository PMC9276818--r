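test_that("config validation enforces the cohort invariants", {
  expect_error(twin_sim_config(var_a = -0.1), "nonnegative")
  expect_error(twin_sim_config(var_e = 0), "strictly positive")
  expect_error(twin_sim_config(var_c = 0.2, var_d = 0.2, var_e = 0.6),
               "ACE or an ADE")
  expect_error(twin_sim_config(n_rated_events = 41), "exceed")
  # fractions rescaled to sum to one
  cfg <- twin_sim_config(var_a = 1, var_c = 0, var_e = 1)
  expect_equal(cfg$var_a + cfg$var_c + cfg$var_d + cfg$var_e, 1)
  expect_equal(cfg$var_a, 0.5)
})

test_that("latent traits realize the twin covariance algebra", {
  # independence world: no within-pair correlation
  n <- 3000
  cfg0 <- twin_sim_config(n_mz_pairs = n, n_dz_pairs = n, var_a = 0,
                          var_c = 0, var_e = 1, seed = 21)
  tr0 <- simulate_latent_traits(cfg0)
  p0 <- suppressMessages(pair_phenotypes(tr0, value_cols = "vividness"))
  for (z in c("MZ", "DZ")) {
    pz <- p0[p0$zygosity == z, ]
    expect_lt(abs(cor(pz$vividness_1, pz$vividness_2)), 3 / sqrt(n))
  }

  # fully additive world: MZ identical, DZ correlated 1/2
  cfg1 <- twin_sim_config(n_mz_pairs = 2000, n_dz_pairs = 2000, var_a = 1,
                          var_c = 0, var_e = 1e-12, seed = 22)
  cfg1$var_a <- 1; cfg1$var_e <- 0  # exact A-only limit
  tr1 <- simulate_latent_traits(cfg1)
  p1 <- suppressMessages(pair_phenotypes(tr1, value_cols = "vividness"))
  mz <- p1[p1$zygosity == "MZ", ]
  expect_equal(mz$vividness_1, mz$vividness_2)
  dz <- p1[p1$zygosity == "DZ", ]
  expect_lt(abs(cor(dz$vividness_1, dz$vividness_2) - 0.5), 0.06)

  # ADE world: cov_MZ = var_a + var_d, cov_DZ = var_a/2 + var_d/4
  cfg2 <- twin_sim_config(n_mz_pairs = 20000, n_dz_pairs = 20000,
                          var_a = 0.3, var_d = 0.3, var_c = 0, var_e = 0.4,
                          seed = 23)
  tr2 <- simulate_latent_traits(cfg2)
  p2 <- suppressMessages(pair_phenotypes(tr2, value_cols = "vividness"))
  mz <- p2[p2$zygosity == "MZ", ]; dz <- p2[p2$zygosity == "DZ", ]
  expect_lt(abs(cov(mz$vividness_1, mz$vividness_2) - 0.6), 0.025)
  expect_lt(abs(cov(dz$vividness_1, dz$vividness_2) - 0.225), 0.025)
})

test_that("trait marginals are standard normal", {
  cfg <- twin_sim_config(n_mz_pairs = 3000, n_dz_pairs = 2000,
                         var_a = 0.4, var_c = 0.2, var_e = 0.4, seed = 31)
  tr <- simulate_latent_traits(cfg)
  for (trait in c("vividness", "learning_rate")) {
    ks <- suppressWarnings(ks.test(tr[[trait]], "pnorm"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(abs(var(tr[[trait]]) - 1), 0.08)
  }
})

test_that("trial records respect the task bounds and rated-event design", {
  cfg <- twin_sim_config(n_mz_pairs = 30, n_dz_pairs = 15, seed = 5)
  study <- simulate_twin_study(cfg)
  tr <- study$trials
  expect_true(all(tr$first_estimate >= 3 & tr$first_estimate <= 77))
  expect_true(all(tr$second_estimate >= 3 & tr$second_estimate <= 77))
  expect_true(all(tr$information >= 10 & tr$information <= 70))
  # exactly n_rated_events rated + recalled events per subject
  expect_true(all(rated_event_counts(tr) == 20))
  rated <- !is.na(tr$vividness)
  expect_identical(rated, !is.na(tr$recalled_probability))
  expect_true(all(tr$vividness[rated] %in% 1:6))
  # both twins of a pair share age and sex
  byp <- split(tr, tr$pair_id)
  expect_true(all(vapply(byp, function(d)
    length(unique(d$age)) == 1 && length(unique(d$sex)) == 1, logical(1))))
})

test_that("perfect learners and perfect memory reach the task ceilings", {
  cfg <- twin_sim_config(n_mz_pairs = 5, n_dz_pairs = 5, trial_noise_sd = 0,
                         seed = 9)
  tr <- simulate_latent_traits(cfg)
  tr$learning_rate <- 50     # pnorm(50) = 1: full update to the information
  tr$memory_fidelity <- 50   # recall always exact
  trials <- simulate_task_trials(tr, cfg)
  expect_true(all(trials$second_estimate == trials$information))
  phen <- subject_phenotypes(trials)
  expect_true(all(phen$memory_score == 100))
})

test_that("learning scores recover the generating learning-rate trait", {
  study <- simulate_twin_study(twin_sim_config(seed = 7))
  phen <- subject_phenotypes(study$trials)
  truth <- study$traits$learning_rate[match(phen$subject_id,
                                            study$traits$subject_id)]
  expect_gt(cor(phen$learning_score, truth, use = "complete.obs"), 0.5)
})

test_that("identical seeds give byte-identical trial files", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_csv(tiny_trials(seed = 42), f1)
  write_trial_csv(tiny_trials(seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  file.remove(f1, f2)
})

test_that("trial CSV round-trips and rejects out-of-range estimates", {
  tr <- tiny_trials()
  f <- tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  back <- read_trial_csv(f)
  expect_equal(back, tr[, names(back)], ignore_attr = TRUE)
  expect_true(all(rated_event_counts(back) == 3))

  bad <- tr
  bad$first_estimate[4] <- 80
  write_trial_csv(bad, f)
  expect_error(read_trial_csv(f), "first_estimate outside \\[3, 77\\].*line 5")
  bad <- tr
  bad$vividness[which(!is.na(bad$vividness))[1]] <- 9
  write_trial_csv(bad, f)
  expect_error(read_trial_csv(f), "vividness")
  file.remove(f)
})
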