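#' Simulation configuration for a synthetic twin cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_latent_traits()] and [simulate_task_trials()]. The defaults
#' reproduce the design of the belief-formation twin study the package
#' analyses: 184 monozygotic (MZ) and 80 dizygotic (DZ) same-sex pairs, 40
#' adverse life events per subject with 20 randomly selected events receiving
#' ratings and a recall probe, probability estimates bounded to [3, 77] and
#' base-rate information bounded to [10, 70].
#'
#' Subject-level latent traits are standardized (unit marginal variance) and
#' decomposed into additive genetic (A), shared environment (C), dominance
#' genetic (D) and unique environment (E) fractions. Within-pair trait
#' covariance is \code{var_a + var_c} for MZ and \code{var_a/2 + var_c} for DZ
#' pairs (ACE worlds), or \code{var_a + var_d} (MZ) and
#' \code{var_a/2 + var_d/4} (DZ) in ADE worlds.
#'
#' @param n_mz_pairs,n_dz_pairs number of MZ / DZ twin pairs.
#' @param n_events events (trials) per subject.
#' @param n_rated_events events per subject receiving ratings and a recall
#'   probe (randomly selected); must not exceed \code{n_events}.
#' @param var_a,var_c,var_d,var_e variance fractions of the latent traits
#'   (additive genetic, shared environment, dominance, unique environment).
#'   Must be nonnegative with \code{var_e > 0}; \code{var_c} and \code{var_d}
#'   may not both be positive (a scenario is either an ACE or an ADE world).
#'   Fractions are rescaled to sum to one.
#' @param trait_list names of the subject-level latent traits.
#' @param trial_noise_sd standard deviation of trial-level estimate noise, in
#'   percentage-point units.
#' @param seed integer seed; mandatory for reproducibility.
#' @param coefficients named list of generative mapping coefficients (loadings
#'   of traits and trial signals onto estimates, sensitivity of learning and
#'   recall to their traits, recall perturbation scale). Recorded here so the
#'   ground-truth phenotypes are recoverable from the configuration.
#'
#' @return an object of class \code{twin_sim_config} (a validated list).
#' @export
twin_sim_config <- function(n_mz_pairs = 184L, n_dz_pairs = 80L,
                            n_events = 40L, n_rated_events = 20L,
                            var_a = 0.35, var_c = 0, var_d = 0, var_e = 0.65,
                            trait_list = c("learning_rate", "vividness",
                                           "negativity", "memory_fidelity",
                                           "prior_offset"),
                            trial_noise_sd = 5, seed = 1L,
                            coefficients = list()) {
  defaults <- list(prior_scale = 8, beta_vividness = 4, beta_negativity = 2,
                   beta_familiarity = 1.5, beta_experience = 1.5,
                   subject_signal_weight = 0.6, base_rate_weight = 0.4,
                   learning_sensitivity = 1, memory_sensitivity = 1,
                   recall_perturb_sd = 8)
  coefficients <- utils::modifyList(defaults, coefficients)

  cfg <- list(n_mz_pairs = as.integer(n_mz_pairs),
              n_dz_pairs = as.integer(n_dz_pairs),
              n_events = as.integer(n_events),
              n_rated_events = as.integer(n_rated_events),
              var_a = var_a, var_c = var_c, var_d = var_d, var_e = var_e,
              trait_list = trait_list,
              trial_noise_sd = trial_noise_sd,
              seed = as.integer(seed),
              coefficients = coefficients)

  if (cfg$n_mz_pairs < 1L || cfg$n_dz_pairs < 0L)
    stop("need at least one MZ pair and a nonnegative number of DZ pairs")
  if (cfg$n_rated_events > cfg$n_events)
    stop("n_rated_events must not exceed n_events")
  v <- c(cfg$var_a, cfg$var_c, cfg$var_d, cfg$var_e)
  if (any(v < 0)) stop("variance fractions must be nonnegative")
  if (cfg$var_e <= 0) stop("var_e must be strictly positive")
  if (cfg$var_c > 0 && cfg$var_d > 0)
    stop("var_c and var_d may not both be positive (choose an ACE or an ADE world)")
  tot <- sum(v)
  if (abs(tot - 1) > 1e-8) {
    cfg$var_a <- cfg$var_a / tot; cfg$var_c <- cfg$var_c / tot
    cfg$var_d <- cfg$var_d / tot; cfg$var_e <- cfg$var_e / tot
  }
  if (cfg$trial_noise_sd < 0) stop("trial_noise_sd must be nonnegative")
  if (is.na(cfg$seed)) stop("seed is mandatory")
  class(cfg) <- "twin_sim_config"
  cfg
}

#' @export
print.twin_sim_config <- function(x, ...) {
  world <- if (x$var_d > 0) "ADE" else "ACE"
  cat(sprintf("Twin cohort simulation config (%s world)\n", world))
  cat(sprintf("  pairs: %d MZ + %d DZ; events: %d (%d rated)\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_events, x$n_rated_events))
  cat(sprintf("  variance fractions: A=%.2f C=%.2f D=%.2f E=%.2f\n",
              x$var_a, x$var_c, x$var_d, x$var_e))
  cat(sprintf("  trial noise sd: %.2f; seed: %d\n", x$trial_noise_sd, x$seed))
  invisible(x)
}

# truncated-normal draw by rejection; bounds wide enough that this terminates fast
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Simulate subject-level latent traits for a twin cohort
#'
#' Draws standardized latent traits with the twin covariance structure implied
#' by the biometric model: the additive genetic component is fully shared
#' within MZ pairs while DZ twins receive
#' \eqn{A = \sqrt{1/2}\,shared + \sqrt{1/2}\,unique}; the shared-environment
#' component is common to both twins of a pair; dominance is fully shared for
#' MZ and correlated 1/4 for DZ; the unique-environment component is
#' independent per twin. Each trait has unit marginal variance, so the
#' within-pair covariance equals \code{var_a + var_c} (MZ) and
#' \code{var_a/2 + var_c} (DZ), or the ADE analogues when \code{var_d > 0}.
#'
#' Pair-level demographics mimic the study cohort: both twins share one age
#' drawn from a normal(52, 14) truncated to [18, 90] and rounded to whole
#' years, and pairs are female with probability 0.88 (same-sex pairs only).
#'
#' @param config a [twin_sim_config()] object.
#' @return a data.frame with one row per subject: \code{subject_id},
#'   \code{pair_id}, \code{zygosity}, \code{twin} (1 or 2), \code{age},
#'   \code{sex} ("F"/"M"), and one column per latent trait.
#' @export
simulate_latent_traits <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  set.seed(config$seed)
  va <- config$var_a; vc <- config$var_c; vd <- config$var_d; ve <- config$var_e

  draw_zyg <- function(np, zyg) {
    traits <- lapply(config$trait_list, function(tr) {
      a_s <- stats::rnorm(np)
      if (zyg == "MZ") {
        a1 <- a_s; a2 <- a_s
      } else {
        a1 <- sqrt(0.5) * a_s + sqrt(0.5) * stats::rnorm(np)
        a2 <- sqrt(0.5) * a_s + sqrt(0.5) * stats::rnorm(np)
      }
      d_s <- stats::rnorm(np)
      if (zyg == "MZ") {
        d1 <- d_s; d2 <- d_s
      } else {
        d1 <- 0.5 * d_s + sqrt(0.75) * stats::rnorm(np)
        d2 <- 0.5 * d_s + sqrt(0.75) * stats::rnorm(np)
      }
      c_s <- stats::rnorm(np)
      t1 <- sqrt(va) * a1 + sqrt(vc) * c_s + sqrt(vd) * d1 + sqrt(ve) * stats::rnorm(np)
      t2 <- sqrt(va) * a2 + sqrt(vc) * c_s + sqrt(vd) * d2 + sqrt(ve) * stats::rnorm(np)
      cbind(t1, t2)
    })
    names(traits) <- config$trait_list
    traits
  }

  build_df <- function(traits, np, zyg, pair_offset) {
    if (np == 0L) return(NULL)
    age <- round(.rtrunc_norm(np, 52, 14, 18, 90))
    sex <- ifelse(stats::runif(np) < 0.88, "F", "M")
    pair_id <- sprintf("P%04d", pair_offset + seq_len(np))
    df <- data.frame(
      subject_id = sprintf("%s-%d", rep(pair_id, each = 2L), rep(1:2, np)),
      pair_id = rep(pair_id, each = 2L),
      zygosity = zyg,
      twin = rep(1:2, np),
      age = rep(age, each = 2L),
      sex = rep(sex, each = 2L),
      stringsAsFactors = FALSE)
    for (tr in config$trait_list) {
      m <- traits[[tr]]
      df[[tr]] <- as.vector(t(m))  # interleave twin1, twin2
    }
    df
  }

  mz <- build_df(draw_zyg(config$n_mz_pairs, "MZ"), config$n_mz_pairs, "MZ", 0L)
  dz <- build_df(draw_zyg(config$n_dz_pairs, "DZ"), config$n_dz_pairs, "DZ",
                 config$n_mz_pairs)
  out <- rbind(mz, dz)
  rownames(out) <- NULL
  out
}

# map a continuous latent signal onto the 1-6 rating scale by fixed
# standard-normal quantile bins
.discretize_rating <- function(z) {
  cuts <- stats::qnorm(seq_len(5) / 6)
  findInterval(z, cuts) + 1L
}

.clip_round <- function(x, lo = 3, hi = 77) pmin(hi, pmax(lo, round(x)))

#' Simulate trial-level belief-formation task data
#'
#' Generates one row per subject x event mimicking the task: a first
#' probability estimate (prior), presented base-rate information, a second
#' estimate (posterior), and — for a random subset of events per subject —
#' four 1-6 ratings (familiarity, past experience, vividness, negativity) and
#' a recall probe of the presented information.
#'
#' The generative equations are deliberately minimal and linear with clipping,
#' with every coefficient exposed in \code{config$coefficients}: the first
#' estimate is the event base rate plus a subject prior offset, plus
#' trial-level vividness/negativity/familiarity/experience signals (each a
#' mixture of the subject trait and trial noise) with the configured loadings,
#' plus Gaussian noise; the second estimate moves a fraction
#' \code{pnorm(learning_sensitivity * learning_rate)} of the way from the
#' first estimate toward the information; recall reproduces the information
#' exactly with probability \code{pnorm(memory_sensitivity * memory_fidelity)}
#' and is otherwise perturbed; ratings are the trial signals discretized onto
#' 1-6 by fixed standard-normal quantile bins. Estimates are rounded and
#' clipped to [3, 77]; base rates are integers in [10, 70] shared by all
#' subjects.
#'
#' @param traits output of [simulate_latent_traits()].
#' @param config the [twin_sim_config()] used to generate \code{traits}.
#' @return a data.frame of trial records with columns \code{subject_id},
#'   \code{pair_id}, \code{zygosity}, \code{age}, \code{sex}, \code{event_id},
#'   \code{first_estimate}, \code{information}, \code{second_estimate},
#'   \code{recalled_probability}, \code{familiarity}, \code{past_experience},
#'   \code{vividness}, \code{negativity} (ratings/recall \code{NA} on unrated
#'   events).
#' @export
simulate_task_trials <- function(traits, config) {
  stopifnot(inherits(config, "twin_sim_config"), is.data.frame(traits))
  need <- c("learning_rate", "vividness", "negativity", "memory_fidelity",
            "prior_offset")
  if (!all(need %in% names(traits)))
    stop("traits must contain the canonical trait columns: ",
         paste(need, collapse = ", "))
  set.seed(config$seed + 1L)
  co <- config$coefficients
  ns <- nrow(traits)
  ne <- config$n_events

  base <- sample(10:70, ne, replace = TRUE)
  base_z <- if (stats::sd(base) > 0) (base - mean(base)) / stats::sd(base) else base * 0

  # subject x event matrices
  n_cells <- ns * ne
  w <- co$subject_signal_weight
  mix <- function(trait) {
    w * rep(trait, each = ne) + sqrt(1 - w^2) * stats::rnorm(n_cells)
  }
  v_sig <- mix(traits$vividness)
  n_sig <- mix(traits$negativity)
  bw <- co$base_rate_weight
  f_sig <- bw * rep(base_z, ns) + sqrt(1 - bw^2) * stats::rnorm(n_cells)
  x_sig <- bw * rep(base_z, ns) + sqrt(1 - bw^2) * stats::rnorm(n_cells)

  noise <- function() if (config$trial_noise_sd > 0)
    stats::rnorm(n_cells, 0, config$trial_noise_sd) else 0

  first_raw <- rep(base, ns) +
    co$prior_scale * rep(traits$prior_offset, each = ne) +
    co$beta_vividness * v_sig - co$beta_negativity * n_sig +
    co$beta_familiarity * f_sig + co$beta_experience * x_sig + noise()
  first <- .clip_round(first_raw)
  info <- rep(base, ns)

  alpha <- stats::pnorm(co$learning_sensitivity * traits$learning_rate)
  second <- .clip_round(first + rep(alpha, each = ne) * (info - first) + noise())

  # per-subject random choice of rated events
  rated <- logical(n_cells)
  for (i in seq_len(ns)) {
    idx <- (i - 1L) * ne + sample.int(ne, config$n_rated_events)
    rated[idx] <- TRUE
  }

  p_mem <- stats::pnorm(co$memory_sensitivity * traits$memory_fidelity)
  hit <- stats::runif(n_cells) < rep(p_mem, each = ne)
  delta <- round(stats::rnorm(n_cells, 0, co$recall_perturb_sd))
  delta[delta == 0] <- 1L
  recall <- ifelse(hit, info, .clip_round(info + delta))
  recall[!rated] <- NA

  ratings <- list(familiarity = f_sig, past_experience = x_sig,
                  vividness = v_sig, negativity = n_sig)
  ratings <- lapply(ratings, function(z) {
    r <- .discretize_rating(z); r[!rated] <- NA; r
  })

  out <- data.frame(
    subject_id = rep(traits$subject_id, each = ne),
    pair_id = rep(traits$pair_id, each = ne),
    zygosity = rep(traits$zygosity, each = ne),
    age = rep(traits$age, each = ne),
    sex = rep(traits$sex, each = ne),
    event_id = rep(seq_len(ne), ns),
    first_estimate = first,
    information = info,
    second_estimate = second,
    recalled_probability = recall,
    familiarity = ratings$familiarity,
    past_experience = ratings$past_experience,
    vividness = ratings$vividness,
    negativity = ratings$negativity,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a complete twin study
#'
#' Convenience wrapper running [simulate_latent_traits()] then
#' [simulate_task_trials()].
#'
#' @inheritParams simulate_latent_traits
#' @return list with elements \code{traits} and \code{trials}.
#' @export
simulate_twin_study <- function(config = twin_sim_config()) {
  traits <- simulate_latent_traits(config)
  trials <- simulate_task_trials(traits, config)
  list(traits = traits, trials = trials, config = config)
}

.trial_columns <- c("subject_id", "pair_id", "zygosity", "age", "sex",
                    "event_id", "first_estimate", "information",
                    "second_estimate", "recalled_probability", "familiarity",
                    "past_experience", "vividness", "negativity")

#' Write / read trial-level task data as CSV
#'
#' One row per subject x event; missing ratings and recalls are encoded as
#' empty cells. `read_trial_csv()` validates ranges on read: estimates must
#' lie in [3, 77], information in [10, 70] and ratings in 1-6; violations
#' raise an error naming the offending file lines.
#'
#' @param records trial data.frame as produced by [simulate_task_trials()].
#' @param path file path.
#' @return `read_trial_csv()` returns the validated trial data.frame.
#' @export
write_trial_csv <- function(records, path) {
  stopifnot(all(.trial_columns %in% names(records)))
  utils::write.csv(records[, .trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       pair_id = "character",
                                       zygosity = "character",
                                       sex = "character"))
  missing_cols <- setdiff(.trial_columns, names(df))
  if (length(missing_cols))
    stop("trial CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  # +1 for the header row so reported numbers are file line numbers
  line_of <- function(i) i + 1L
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s at line%s %s", what, if (length(i) > 1) "s" else "",
                   paste(utils::head(line_of(i), 10L), collapse = ", ")))
  }
  for (col in c("first_estimate", "second_estimate"))
    bad(!is.na(df[[col]]) & (df[[col]] < 3 | df[[col]] > 77),
        sprintf("%s outside [3, 77]", col))
  bad(!is.na(df$information) & (df$information < 10 | df$information > 70),
      "information outside [10, 70]")
  for (col in c("familiarity", "past_experience", "vividness", "negativity"))
    bad(!is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 6 |
                               df[[col]] != round(df[[col]])),
        sprintf("%s not an integer in 1-6", col))
  bad(!df$zygosity %in% c("MZ", "DZ"), "zygosity not MZ/DZ")
  df
}

#' Rated-event counts per subject
#'
#' Number of events per subject carrying a recall response (the rated subset).
#'
#' @param trials trial data.frame.
#' @return named integer vector, one entry per subject.
#' @export
rated_event_counts <- function(trials) {
  tapply(!is.na(trials$recalled_probability), trials$subject_id, sum)
}
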