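# Shared fixtures and independent oracles, all built in code at test time.

# Latent-trait cohort reshaped so that one trait can be analysed as the
# "vividness" phenotype (unit-variance, known A/C/D/E ground truth).
trait_pairs <- function(n_mz = 184, n_dz = 80, var_a = 0.35, var_c = 0,
                        var_d = 0, var_e = 0.65, seed = 1) {
  cfg <- twin_sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                         var_a = var_a, var_c = var_c, var_d = var_d,
                         var_e = var_e, seed = seed)
  tr <- simulate_latent_traits(cfg)
  p <- suppressMessages(pair_phenotypes(tr, value_cols = "vividness"))
  names(p) <- sub("^vividness_", "vividness_mean_", names(p))
  p
}

# Independent deviance oracle: exhaustive grid search over the ACE variance
# components using sufficient statistics for the mean-only model. Returns the
# minimum -2 log-likelihood over the grid.
grid_deviance_min <- function(pairs, pcol = "vividness_mean", res = 0.01) {
  y1 <- pairs[[paste0(pcol, "_1")]]
  y2 <- pairs[[paste0(pcol, "_2")]]
  zyg <- pairs$zygosity
  st <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    i <- zyg == z
    list(n = sum(i), T = sum(y1[i] + y2[i]),
         qs = sum(y1[i]^2 + y2[i]^2), qo = sum(y1[i] * y2[i]))
  })
  vy <- stats::var(c(y1, y2))
  hi <- ceiling(1.5 * vy / res) * res
  g <- expand.grid(va = seq(0, hi, res), vc = seq(0, hi, res),
                   ve = seq(res, hi, res))
  s <- g$va + g$vc + g$ve
  A <- 0; b <- 0; qf <- 0; ldet <- 0; N <- 0; ok <- rep(TRUE, nrow(g))
  for (z in c("MZ", "DZ")) {
    R <- if (z == "MZ") 1 else 0.5
    o <- R * g$va + g$vc
    det <- s^2 - o^2
    ok <- ok & det > 0
    ws <- s / det; wo <- -o / det
    A <- A + (ws + wo) * 2 * st[[z]]$n
    b <- b + (ws + wo) * st[[z]]$T
    qf <- qf + ws * st[[z]]$qs + 2 * wo * st[[z]]$qo
    ldet <- ldet + st[[z]]$n * log(det)
    N <- N + 2 * st[[z]]$n
  }
  mu <- b / A
  dev <- ldet + (qf - b * mu) + N * log(2 * pi)
  dev[!ok | !is.finite(dev)] <- Inf
  min(dev)
}

# Textbook recursive partial-correlation formula (single covariate):
# r_xy.z = (r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2))
recursive_partial_cor <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# One-way ANOVA intraclass correlation estimator for pairs (k = 2).
anova_icc <- function(p1, p2) {
  n <- length(p1)
  m <- (p1 + p2) / 2
  grand <- mean(c(p1, p2))
  msb <- 2 * sum((m - grand)^2) / (n - 1)
  msw <- sum((p1 - m)^2 + (p2 - m)^2) / n
  (msb - msw) / (msb + msw)
}

# Small deterministic trial table for CSV round-trip checks.
tiny_trials <- function(seed = 42) {
  cfg <- twin_sim_config(n_mz_pairs = 3, n_dz_pairs = 2, n_events = 5,
                         n_rated_events = 3, seed = seed)
  simulate_task_trials(simulate_latent_traits(cfg), cfg)
}
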