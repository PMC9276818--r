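#' Default mean-model covariates for a biometric fit
#'
#' Age, sex, their interaction, and the per-subject control factors used in
#' the twin-similarity analysis (prior, ratings, memory; estimation error for
#' the update phenotype; memory omitted for the prior), minus the focal
#' phenotype itself.
#'
#' @inheritParams control_factors
#' @return character vector of covariate names.
#' @export
default_biometric_covariates <- function(phenotype) {
  c("age", "sex", "age_x_sex", control_factors(phenotype))
}

.varcomp_sets <- list(ACE = c("A", "C", "E"), ADE = c("A", "D", "E"),
                      AE = c("A", "E"), CE = c("C", "E"), E = "E")

# ---- data preparation --------------------------------------------------------

# Builds per-zygosity sufficient statistics for the pair bivariate-normal
# likelihood with a linear mean model shared by both twins. X matrices carry
# an intercept column first; covariates are standardized for conditioning and
# the back-transform stored.
.prep_biometric <- function(pairs, phenotype, covariates) {
  pcol <- .phenotype_cols[[phenotype]]
  y1 <- pairs[[paste0(pcol, "_1")]]
  y2 <- pairs[[paste0(pcol, "_2")]]

  covariates <- covariates %||% character(0)
  per_twin <- function(cv, m) {
    switch(cv,
           age = pairs$age,
           sex = as.numeric(pairs$sex == "F"),
           age_x_sex = pairs$age * as.numeric(pairs$sex == "F"),
           pairs[[paste0(.phenotype_cols[[cv]], "_", m)]])
  }
  X1 <- do.call(cbind, lapply(covariates, per_twin, m = 1L))
  X2 <- do.call(cbind, lapply(covariates, per_twin, m = 2L))
  if (is.null(X1)) {
    X1 <- matrix(numeric(0), length(y1), 0)
    X2 <- matrix(numeric(0), length(y1), 0)
  }
  colnames(X1) <- colnames(X2) <- covariates

  keep <- stats::complete.cases(cbind(y1, y2, X1, X2))
  n_dropped <- sum(!keep)
  y1 <- y1[keep]; y2 <- y2[keep]
  X1 <- X1[keep, , drop = FALSE]; X2 <- X2[keep, , drop = FALSE]
  zyg <- pairs$zygosity[keep]

  # standardize covariates over all subjects (constant columns dropped)
  ctr <- scl <- numeric(0)
  drop_cols <- integer(0)
  for (j in seq_len(ncol(X1))) {
    v <- c(X1[, j], X2[, j])
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) { drop_cols <- c(drop_cols, j); next }
    X1[, j] <- (X1[, j] - m) / s
    X2[, j] <- (X2[, j] - m) / s
    ctr <- c(ctr, m); scl <- c(scl, s)
  }
  if (length(drop_cols)) {
    message("dropping constant covariate(s): ",
            paste(covariates[drop_cols], collapse = ", "))
    X1 <- X1[, -drop_cols, drop = FALSE]
    X2 <- X2[, -drop_cols, drop = FALSE]
    covariates <- covariates[-drop_cols]
  }
  names(ctr) <- names(scl) <- covariates

  M1 <- cbind(1, X1); M2 <- cbind(1, X2)
  groups <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    i <- zyg == z
    if (!any(i)) return(NULL)
    m1 <- M1[i, , drop = FALSE]; m2 <- M2[i, , drop = FALSE]
    yy1 <- y1[i]; yy2 <- y2[i]
    list(n = sum(i),
         S_same = crossprod(m1) + crossprod(m2),
         S_cross = crossprod(m1, m2) + crossprod(m2, m1),
         u_same = crossprod(m1, yy1) + crossprod(m2, yy2),
         u_cross = crossprod(m1, yy2) + crossprod(m2, yy1),
         q_same = sum(yy1^2 + yy2^2),
         q_cross = sum(yy1 * yy2),
         y1 = yy1, y2 = yy2)
  })
  groups <- groups[!vapply(groups, is.null, logical(1))]
  list(groups = groups, p = ncol(M1), n_pairs = length(y1),
       n_dropped = n_dropped, covariates = covariates,
       center = ctr, scale = scl, var_y = stats::var(c(y1, y2)),
       phenotype = phenotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- likelihood --------------------------------------------------------------

# -2 log likelihood at given variance components, with the mean parameters
# (intercept + covariate coefficients) profiled out by closed-form GLS.
# family "ACE" -> off-diagonal R*va + vc; "ADE" -> R*va + D*vd (D = 1 MZ,
# 1/4 DZ). Returns list(neg2ll, gamma).
.neg2ll_gls <- function(dat, va, vc, vd, ve, family) {
  s <- va + vc + vd + ve
  A <- matrix(0, dat$p, dat$p); b <- numeric(dat$p)
  qf <- 0; ldet <- 0; N <- 0
  for (z in names(dat$groups)) {
    g <- dat$groups[[z]]
    R <- if (z == "MZ") 1 else 0.5
    D <- if (z == "MZ") 1 else 0.25
    o <- if (family == "ADE") R * va + D * vd else R * va + vc
    det <- s^2 - o^2
    if (s <= 0 || det <= 1e-300) return(list(neg2ll = 1e10, gamma = NULL))
    w_s <- s / det; w_o <- -o / det
    A <- A + w_s * g$S_same + w_o * g$S_cross
    b <- b + w_s * g$u_same + w_o * g$u_cross
    qf <- qf + w_s * g$q_same + 2 * w_o * g$q_cross
    ldet <- ldet + g$n * log(det)
    N <- N + 2 * g$n
  }
  gamma <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(gamma)) return(list(neg2ll = 1e10, gamma = NULL))
  Q <- qf - sum(b * gamma)
  list(neg2ll = ldet + Q + N * log(2 * pi), gamma = drop(gamma))
}

# path-coefficient parameterization: variances are squares, so nonnegativity
# needs no explicit constraint; sigma_E^2 floored.
.theta_to_v <- function(theta, model, floor_e) {
  v <- c(A = 0, C = 0, D = 0, E = 0)
  comps <- .varcomp_sets[[model]]
  v[comps] <- theta^2
  v["E"] <- max(v["E"], floor_e)
  v
}

.family_of <- function(model) if (model == "ADE") "ADE" else "ACE"

#' Pair log-likelihood under a biometric covariance structure
#'
#' Log-density of each twin pair's phenotype values under the bivariate
#' normal implied by the variance components: diagonal
#' \eqn{\sigma_A^2 + \sigma_C^2 + \sigma_D^2 + \sigma_E^2}, off-diagonal
#' \eqn{R\sigma_A^2 + \sigma_C^2} (ACE family, genetic relatedness R = 1 for
#' MZ, 1/2 for DZ) or \eqn{R\sigma_A^2 + D\sigma_D^2} (ADE family, dominance
#' coefficient D = 1 for MZ, 1/4 for DZ). With all cross-twin components at
#' zero the likelihood factorizes into two univariate normals. A
#' non-positive-definite covariance yields \code{-Inf} with attribute
#' \code{not_pd = TRUE}.
#'
#' @param y1,y2 phenotype values of the two pair members.
#' @param zygosity "MZ"/"DZ" per pair.
#' @param sigma2_a,sigma2_c,sigma2_d,sigma2_e variance components (>= 0).
#' @param mean1,mean2 per-member means (default 0).
#' @param family \code{"ACE"} (cross-twin C) or \code{"ADE"} (cross-twin D).
#' @return numeric vector of per-pair log-likelihood contributions.
#' @export
pair_loglikelihood <- function(y1, y2, zygosity, sigma2_a, sigma2_c = 0,
                               sigma2_d = 0, sigma2_e,
                               mean1 = 0, mean2 = mean1,
                               family = c("ACE", "ADE")) {
  family <- match.arg(family)
  if (any(c(sigma2_a, sigma2_c, sigma2_d, sigma2_e) < 0))
    stop("variance components must be nonnegative")
  s <- sigma2_a + sigma2_c + sigma2_d + sigma2_e
  R <- ifelse(zygosity == "MZ", 1, 0.5)
  D <- ifelse(zygosity == "MZ", 1, 0.25)
  o <- if (family == "ADE") R * sigma2_a + D * sigma2_d else
    R * sigma2_a + sigma2_c
  det <- s^2 - o^2
  if (s <= 0 || any(det <= 0)) {
    out <- rep(-Inf, length(y1))
    attr(out, "not_pd") <- TRUE
    return(out)
  }
  r1 <- y1 - mean1; r2 <- y2 - mean2
  qf <- (s * r1^2 - 2 * o * r1 * r2 + s * r2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * qf
}

# ---- fitting -----------------------------------------------------------------

#' Fit a biometric variance-component model to twin-pair phenotypes
#'
#' Maximum-likelihood fit of one of the ACE-family (ACE, AE, CE, E) or
#' ADE-family (ADE) models. Each pair contributes a bivariate normal
#' likelihood with mean \eqn{\mu + X\beta} per twin (identical coefficients
#' for both twins) and covariance matrix with diagonal
#' \eqn{\sigma_A^2 + \sigma_C^2 + \sigma_D^2 + \sigma_E^2} and off-diagonal
#' \eqn{R\sigma_A^2 + \sigma_C^2} (ACE family) or
#' \eqn{R\sigma_A^2 + D\sigma_D^2} (ADE family), where the genetic
#' relatedness \eqn{R} is 1 for MZ and 1/2 for DZ pairs and the dominance
#' coefficient \eqn{D} is 1 for MZ and 1/4 for DZ.
#'
#' Variances are parameterized as squared path coefficients (guaranteeing
#' nonnegativity); the mean parameters are profiled out in closed form by
#' generalized least squares at every variance evaluation; optimization is
#' multi-start (equal-split, moment-based, nested-zero and random starts)
#' Nelder-Mead with a BFGS polish. \eqn{\sigma_E^2} is floored at
#' \code{1e-6} times the phenotypic variance. Dominance-only (DE) models are
#' rejected: dominance effects are not estimable without additive ones.
#'
#' @param pairs output of [pair_phenotypes()].
#' @param phenotype focal phenotype name (see [control_factors()]).
#' @param model one of \code{"ACE"}, \code{"ADE"}, \code{"AE"}, \code{"CE"},
#'   \code{"E"}.
#' @param covariates mean-model covariate names from \code{age}, \code{sex},
#'   \code{age_x_sex} and the phenotype control factors; \code{NULL} for
#'   none. See [default_biometric_covariates()].
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the random starts.
#' @return object of class \code{biometric_fit}: raw variance components
#'   (\code{sigma2}), standardized percentages (\code{standardized}, summing
#'   to 100 over the components of the model), \code{mu} and covariate
#'   coefficients on the original scale, \code{minus2LL}, \code{ep}
#'   (intercept + variance components), \code{df} (subjects used minus
#'   \code{ep}), \code{aic = minus2LL + 2 ep}, convergence and zero-boundary
#'   flags.
#' @export
fit_biometric <- function(pairs, phenotype, model = "ACE",
                          covariates = NULL, n_starts = 5L, seed = 1L) {
  if (identical(toupper(model), "DE"))
    stop("DE models are not estimable: dominance genetic effects cannot be ",
         "estimated without additive ones")
  model <- match.arg(toupper(model), names(.varcomp_sets))
  phenotype <- match.arg(phenotype, names(.phenotype_cols))
  dat <- .prep_biometric(pairs, phenotype, covariates)
  if (dat$n_pairs < 20)
    stop("need at least 20 complete pairs; have ", dat$n_pairs)
  if (model %in% c("ACE", "ADE", "AE") && length(dat$groups) < 2)
    stop("both zygosities are required to separate A from C/D")
  fit <- .fit_varcomp(dat, model, n_starts = n_starts, seed = seed)
  .as_biometric_fit(fit, dat, model, phenotype)
}

# internal optimizer over path coefficients; returns list(v, neg2ll, gamma,
# converged)
.fit_varcomp <- function(dat, model, n_starts = 5L, seed = 1L) {
  family <- .family_of(model)
  floor_e <- 1e-6 * dat$var_y
  comps <- .varcomp_sets[[model]]
  k <- length(comps)
  obj <- function(theta) {
    v <- .theta_to_v(theta, model, floor_e)
    .neg2ll_gls(dat, v["A"], v["C"], v["D"], v["E"], family)$neg2ll
  }

  # residual moment starts: within-pair covariances of OLS residuals
  res <- local({
    # OLS residuals of stacked subjects on the (standardized) covariates
    g <- dat$groups
    y <- unlist(lapply(g, function(x) c(x$y1, x$y2)))
    v0 <- .neg2ll_gls(dat, 0, 0, 0, stats::var(y), family)
    list(var = stats::var(y))
  })
  covs <- vapply(c("MZ", "DZ"), function(z) {
    g <- dat$groups[[z]]
    if (is.null(g) || g$n < 3) return(NA_real_)
    stats::cov(g$y1, g$y2)
  }, numeric(1))
  vy <- res$var
  a2 <- if (!any(is.na(covs))) max(2 * (covs["MZ"] - covs["DZ"]), 0.01 * vy)
        else 0.3 * vy
  c2 <- if (!any(is.na(covs))) max(2 * covs["DZ"] - covs["MZ"], 0.01 * vy)
        else 0.3 * vy
  e2 <- max(vy - a2 - c2, 0.05 * vy)

  start_list <- list(rep(sqrt(vy / k), k))
  mom <- switch(model,
                ACE = c(sqrt(a2), sqrt(c2), sqrt(e2)),
                ADE = c(sqrt(a2), sqrt(c2), sqrt(e2)),
                AE = c(sqrt(min(a2 + c2, 0.95 * vy)), sqrt(e2)),
                CE = c(sqrt(min(a2 + c2, 0.95 * vy)), sqrt(e2)),
                E = sqrt(vy))
  start_list <- c(start_list, list(mom))
  if (k == 3)  # nested start: middle component at (near) zero
    start_list <- c(start_list, list(c(mom[1], 1e-4 * sqrt(vy), mom[3])))
  set.seed(seed)
  while (length(start_list) < n_starts)
    start_list <- c(start_list,
                    list(sqrt(vy) * abs(stats::rnorm(k, 0.5, 0.3)) + 1e-3))

  best <- NULL
  for (st in start_list) {
    o <- if (k == 1) {
      opt <- stats::optimize(function(t) obj(t), c(sqrt(floor_e), 4 * sqrt(vy)))
      list(par = opt$minimum, value = opt$objective, convergence = 0L)
    } else {
      o1 <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
      o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                                  control = list(maxit = 200,
                                                 reltol = 1e-12)),
                     error = function(e) o1)
      if (o2$value <= o1$value) o2 else o1
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("biometric fit failed to converge from any start")
  v <- .theta_to_v(best$par, model, floor_e)
  ll <- .neg2ll_gls(dat, v[["A"]], v[["C"]], v[["D"]], v[["E"]], family)
  list(v = v, neg2ll = unname(ll$neg2ll), gamma = ll$gamma,
       converged = isTRUE(best$convergence == 0L))
}

.as_biometric_fit <- function(fit, dat, model, phenotype) {
  comps <- .varcomp_sets[[model]]
  v <- fit$v
  total <- sum(v[comps])
  std <- stats::setNames(rep(0, 4), c("A", "C", "D", "E"))
  std[comps] <- 100 * v[comps] / total
  ep <- 1L + length(comps)
  n_subjects <- 2L * dat$n_pairs
  gamma <- fit$gamma
  # back-transform the mean model to the original covariate scale
  beta_std <- gamma[-1]
  beta <- if (length(beta_std)) beta_std / dat$scale else numeric(0)
  names(beta) <- dat$covariates
  mu <- gamma[1] - if (length(beta_std))
    sum(beta_std * dat$center / dat$scale) else 0
  structure(list(
    model = model, phenotype = phenotype, covariates = dat$covariates,
    mu = unname(mu), beta = beta,
    sigma2 = v, standardized = std,
    minus2LL = fit$neg2ll, ep = ep, df = n_subjects - ep,
    aic = fit$neg2ll + 2 * ep,
    n_pairs = dat$n_pairs, n_subjects = n_subjects,
    n_dropped = dat$n_dropped,
    converged = fit$converged,
    boundary = std[comps] < 0.1 & comps != "E",
    .data = dat), class = "biometric_fit")
}

#' @export
print.biometric_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Biometric %s fit: phenotype '%s' (%d pairs, %d subjects)\n",
              x$model, x$phenotype, x$n_pairs, x$n_subjects))
  comps <- .varcomp_sets[[x$model]]
  est <- paste(sprintf("%s = %.1f%%", comps, x$standardized[comps]),
               collapse = ", ")
  cat("  standardized components:", est, "\n")
  cat(sprintf("  -2LL = %.*f, ep = %d, df = %d, AIC = %.*f\n",
              digits, x$minus2LL, x$ep, x$df, digits, x$aic))
  if (length(x$covariates))
    cat("  mean-model covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (any(x$boundary))
    cat("  note: component(s) at the zero boundary:",
        paste(comps[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

# ---- profile-likelihood confidence intervals ---------------------------------

# deviance profile over the standardized share h of `component`, re-maximizing
# the remaining free parameters (total variance, split of the remainder, and
# the GLS mean model).
.profile_dev <- function(fit, component, h) {
  dat <- fit$.data
  model <- fit$model
  family <- .family_of(model)
  comps <- .varcomp_sets[[model]]
  others <- setdiff(comps, component)
  floor_e <- 1e-6 * dat$var_y
  t_hat <- sum(fit$sigma2[comps])

  n2 <- function(v) .neg2ll_gls(dat, v["A"], v["C"], v["D"], v["E"],
                                family)$neg2ll
  make_v <- function(tot, phi = NULL) {
    v <- c(A = 0, C = 0, D = 0, E = 0)
    v[component] <- h * tot
    rem <- (1 - h) * tot
    if (length(others) == 1) {
      v[others] <- rem
    } else {
      v[others[1]] <- rem * phi
      v[others[2]] <- rem * (1 - phi)
    }
    v["E"] <- max(v["E"], floor_e)
    v
  }
  if (length(others) == 0) return(n2(make_v(t_hat)))
  if (length(others) == 1) {
    opt <- stats::optimize(function(lt) n2(make_v(exp(lt))),
                           log(t_hat) + c(-4, 4))
    return(opt$objective)
  }
  # two remaining components: optimize log-total and logit-split
  phi_hat <- {
    r <- fit$sigma2[others]
    if (sum(r) > 0) max(min(r[1] / sum(r), 1 - 1e-6), 1e-6) else 0.5
  }
  obj <- function(p) n2(make_v(exp(p[1]), stats::plogis(p[2])))
  st <- c(log(t_hat), stats::qlogis(phi_hat))
  o <- stats::optim(st, obj, method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-10))
  o$value
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' The interval contains the standardized component values (in percent of the
#' residual phenotypic variance) whose profiled deviance exceeds the minimum
#' by at most the chi-square(1) quantile for the requested level (3.841 at
#' 95%). Bounds are truncated to [0, 100]; a lower bound collapsing onto the
#' nonnegativity boundary is reported as 0. For the single-component E model
#' the interval is degenerate at 100%.
#'
#' @param fit a [fit_biometric()] result.
#' @param component which component(s); default all components of the model.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns \code{component}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{boundary_lower}, \code{boundary_upper}.
#' @export
profile_ci <- function(fit, component = NULL, level = 0.95) {
  stopifnot(inherits(fit, "biometric_fit"))
  comps <- .varcomp_sets[[fit$model]]
  component <- component %||% comps
  component <- match.arg(component, comps, several.ok = TRUE)
  cutoff <- stats::qchisq(level, 1)
  rows <- lapply(component, function(cm) {
    est <- fit$standardized[cm]
    if (length(comps) == 1)
      return(data.frame(component = cm, estimate = 100, lower = 100,
                        upper = 100, boundary_lower = FALSE,
                        boundary_upper = TRUE, stringsAsFactors = FALSE))
    dmin <- fit$minus2LL
    f <- function(h) .profile_dev(fit, cm, h) - (dmin + cutoff)
    h_hat <- min(max(est / 100, 1e-6), 1 - 1e-6)
    eps <- 1e-6
    f_hat <- f(h_hat)
    if (f_hat > 0) {
      # profile optimum drifted; re-anchor the minimum
      dmin <- dmin + f_hat
      f <- function(h) .profile_dev(fit, cm, h) - (dmin + cutoff)
    }
    lower <- if (h_hat <= 2 * eps || f(eps) <= 0) {
      bl <- TRUE; 0
    } else {
      bl <- FALSE
      100 * stats::uniroot(f, c(eps, h_hat), tol = 1e-5)$root
    }
    upper <- if (h_hat >= 1 - 2 * eps || f(1 - eps) <= 0) {
      bu <- TRUE; 100
    } else {
      bu <- FALSE
      100 * stats::uniroot(f, c(h_hat, 1 - eps), tol = 1e-5)$root
    }
    data.frame(component = cm, estimate = unname(est), lower = lower,
               upper = upper, boundary_lower = bl, boundary_upper = bu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- model selection ---------------------------------------------------------

#' Compare biometric models by AIC
#'
#' Fits each candidate model and ranks them by Akaike information criterion
#' (\code{AIC = -2LL + 2 ep}, smaller is better); ties are broken toward
#' fewer parameters. Non-convergent candidates are excluded with a note.
#'
#' @inheritParams fit_biometric
#' @param models candidate models (default all five).
#' @param ci also compute profile CIs for every fit (slower).
#' @return object of class \code{biometric_selection}: a list with
#'   \code{table} (one row per model, AIC-ascending, winner first),
#'   \code{fits} (named list of \code{biometric_fit}s) and \code{winner}.
#' @export
model_selection <- function(pairs, phenotype,
                            models = c("ACE", "ADE", "AE", "CE", "E"),
                            covariates = NULL, n_starts = 5L, seed = 1L,
                            ci = FALSE) {
  fits <- list(); notes <- character(0)
  for (m in models) {
    f <- tryCatch(fit_biometric(pairs, phenotype, model = m,
                                covariates = covariates,
                                n_starts = n_starts, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      notes <- c(notes, sprintf("%s excluded: %s", m, conditionMessage(f)))
    } else fits[[m]] <- f
  }
  if (!length(fits)) stop("no candidate model converged")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, A = f$standardized["A"],
               D = f$standardized["D"], C = f$standardized["C"],
               E = f$standardized["E"], AIC = f$aic, minus2LL = f$minus2LL,
               ep = f$ep, df = f$df, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$AIC, tab$ep), ]
  tab$winner <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  if (ci) for (m in names(fits)) fits[[m]]$ci <- profile_ci(fits[[m]])
  structure(list(table = tab, fits = fits, winner = tab$model[1],
                 notes = notes, phenotype = phenotype),
            class = "biometric_selection")
}

#' @export
print.biometric_selection <- function(x, ...) {
  cat(sprintf("Biometric model comparison: phenotype '%s' (winner: %s)\n",
              x$phenotype, x$winner))
  print(format(x$table, digits = 4), row.names = FALSE)
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "\n   "), "\n")
  invisible(x)
}

#' Biometric fits on event subsets
#'
#' Recomputes the per-subject phenotypes on each subset of events and runs
#' the full phenotype-to-fit chain per subset (for example, splitting events
#' into those with and without a known genetic predisposition).
#'
#' @param trials trial-level data.frame.
#' @param event_subsets named list of event-id vectors partitioning (or
#'   selecting from) the events.
#' @param phenotype focal phenotype name.
#' @param model biometric model to fit (default \code{"AE"}).
#' @param covariates mean-model covariates (default none).
#' @param memory_tolerance recall tolerance for the recomputed phenotypes.
#' @param ... further arguments passed to [fit_biometric()].
#' @return named list of \code{biometric_fit} objects, one per subset.
#' @export
stratified_fit <- function(trials, event_subsets, phenotype, model = "AE",
                           covariates = NULL, memory_tolerance = 0, ...) {
  stopifnot(is.list(event_subsets), !is.null(names(event_subsets)))
  out <- lapply(event_subsets, function(ev) {
    sub <- trials[trials$event_id %in% ev, , drop = FALSE]
    per_subj <- table(sub$subject_id)
    if (length(per_subj) && stats::median(per_subj) < 5)
      warning("event subset leaves fewer than 5 events per subject")
    phen <- subject_phenotypes(sub, memory_tolerance = memory_tolerance)
    pairs <- pair_phenotypes(phen)
    fit_biometric(pairs, phenotype, model = model, covariates = covariates,
                  ...)
  })
  names(out) <- names(event_subsets)
  out
}

#' Falconer heritability approximation
#'
#' Classical approximation \eqn{\hat h^2 = 2 (r_{MZ} - r_{DZ})} from plain
#' (double-entered, orientation-free) within-pair correlations, in percent.
#' Used as a moment cross-check of the maximum-likelihood estimate.
#'
#' @param pairs output of [pair_phenotypes()].
#' @param phenotype focal phenotype name.
#' @return list with \code{r_mz}, \code{r_dz} and \code{a_hat_pct}.
#' @export
falconer_estimate <- function(pairs, phenotype) {
  pcol <- .phenotype_cols[[match.arg(phenotype, names(.phenotype_cols))]]
  r_of <- function(z) {
    pz <- pairs[pairs$zygosity == z, ]
    p1 <- pz[[paste0(pcol, "_1")]]; p2 <- pz[[paste0(pcol, "_2")]]
    ok <- !is.na(p1) & !is.na(p2)
    stats::cor(c(p1[ok], p2[ok]), c(p2[ok], p1[ok]))
  }
  r_mz <- r_of("MZ"); r_dz <- r_of("DZ")
  list(r_mz = r_mz, r_dz = r_dz, a_hat_pct = 200 * (r_mz - r_dz))
}
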