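#' Signed belief update
#'
#' Magnitude of the change from first to second estimate, signed positively
#' when the change is toward the presented information and negatively when it
#' is away from it. Overshooting the information still counts as movement
#' toward it. Trials on which the first estimate equals the information are
#' excluded (returned as \code{NA}): "toward" is undefined there.
#'
#' @param first,second first and second probability estimates, in [3, 77].
#' @param information presented base-rate information, in [10, 70].
#' @return numeric vector of signed updates (\code{NA} where excluded).
#' @export
signed_update <- function(first, second, information) {
  if (any(!is.na(first) & (first < 3 | first > 77)) ||
      any(!is.na(second) & (second < 3 | second > 77)))
    stop("estimates must lie in [3, 77]")
  if (any(!is.na(information) & (information < 10 | information > 70)))
    stop("information must lie in [10, 70]")
  magnitude <- abs(second - first)
  toward <- sign(information - first) * sign(second - first)
  out <- ifelse(toward >= 0, magnitude, -magnitude)
  out[!is.na(first) & first == information] <- NA
  out
}

#' Estimation error
#'
#' Absolute difference between the first estimate and the presented
#' information.
#'
#' @inheritParams signed_update
#' @return nonnegative numeric vector.
#' @export
estimation_error <- function(first, information) {
  abs(first - information)
}

#' Learning score
#'
#' Within-subject product-moment correlation between signed update and
#' estimation error across usable trials. Requires at least \code{min_trials}
#' complete trials and nonzero variance in both series; otherwise returns
#' \code{NA} with a warning.
#'
#' @param update signed updates (from [signed_update()]).
#' @param error estimation errors (from [estimation_error()]).
#' @param min_trials minimum number of usable trials (default 3).
#' @return a correlation in [-1, 1], or \code{NA}.
#' @export
learning_score <- function(update, error, min_trials = 3L) {
  ok <- !is.na(update) & !is.na(error)
  if (sum(ok) < min_trials) {
    warning("fewer than ", min_trials, " usable trials; learning score missing")
    return(NA_real_)
  }
  if (stats::sd(update[ok]) == 0 || stats::sd(error[ok]) == 0) {
    warning("degenerate variance; learning score missing")
    return(NA_real_)
  }
  stats::cor(update[ok], error[ok])
}

#' Memory score
#'
#' Percentage of recall probes on which the recalled probability matches the
#' presented information. A recall counts as correct when
#' \code{|recalled - information| <= tolerance}; the default tolerance of 0
#' requires an exact integer match.
#'
#' @param recalled recalled probabilities (\code{NA} on unprobed trials).
#' @param information presented information.
#' @param tolerance match tolerance in percentage points (default 0 = exact).
#' @return percentage in [0, 100], or \code{NA} when no recall probes exist.
#' @export
memory_score <- function(recalled, information, tolerance = 0) {
  ok <- !is.na(recalled) & !is.na(information)
  if (!any(ok)) return(NA_real_)
  100 * mean(abs(recalled[ok] - information[ok]) <= tolerance)
}

.phenotype_cols <- c(update = "update_mean", learning = "learning_score",
                     memory = "memory_score", prior = "prior_mean",
                     vividness = "vividness_mean", negativity = "negativity_mean",
                     familiarity = "familiarity_mean",
                     experience = "experience_mean", error = "error_mean")

#' Derive per-subject phenotypes from trial-level data
#'
#' Computes, for each subject: mean signed update and the learning score
#' (trials with first estimate equal to the information excluded), the memory
#' score, the mean first estimate (prior), the mean estimation error, and the
#' mean of each 1-6 rating over the rated events. Subjects missing more than
#' \code{1 - min_prop} of a phenotype's inputs receive a missing phenotype
#' rather than a noisy one.
#'
#' @param trials trial data.frame (see [simulate_task_trials()] /
#'   [read_trial_csv()]).
#' @param memory_tolerance recall match tolerance passed to [memory_score()].
#' @param min_prop minimum proportion of non-missing inputs required for a
#'   phenotype (default 0.5).
#' @return data.frame with one row per subject: identifiers, demographics,
#'   \code{n_trials_used} (usable update trials) and the phenotype columns
#'   \code{update_mean}, \code{learning_score}, \code{memory_score},
#'   \code{prior_mean}, \code{error_mean}, \code{vividness_mean},
#'   \code{negativity_mean}, \code{familiarity_mean}, \code{experience_mean}.
#'   The total number of trials excluded because the first estimate equalled
#'   the information is attached as attribute \code{n_excluded_equal}.
#' @export
subject_phenotypes <- function(trials, memory_tolerance = 0, min_prop = 0.5) {
  split_idx <- split(seq_len(nrow(trials)), trials$subject_id)
  n_excluded <- 0L
  rows <- lapply(split_idx, function(idx) {
    tr <- trials[idx, ]
    upd <- suppressWarnings(
      signed_update(tr$first_estimate, tr$second_estimate, tr$information))
    err <- estimation_error(tr$first_estimate, tr$information)
    usable <- !is.na(upd) & !is.na(err)
    n_equal <- sum(!is.na(tr$first_estimate) & !is.na(tr$information) &
                     tr$first_estimate == tr$information)
    n_excluded <<- n_excluded + n_equal

    enough <- function(n_ok, n_all) n_all > 0 && n_ok >= min_prop * n_all
    upd_mean <- if (enough(sum(usable), nrow(tr))) mean(upd[usable]) else NA_real_
    lscore <- if (enough(sum(usable), nrow(tr)))
      suppressWarnings(learning_score(upd, err)) else NA_real_
    err_mean <- if (enough(sum(!is.na(err)), nrow(tr)))
      mean(err, na.rm = TRUE) else NA_real_
    prior_mean <- if (enough(sum(!is.na(tr$first_estimate)), nrow(tr)))
      mean(tr$first_estimate, na.rm = TRUE) else NA_real_

    rated <- !is.na(tr$recalled_probability)
    mem <- if (any(rated))
      memory_score(tr$recalled_probability, tr$information,
                   memory_tolerance) else NA_real_
    rating_mean <- function(col) {
      v <- tr[[col]]
      if (enough(sum(!is.na(v)), sum(rated))) mean(v, na.rm = TRUE) else NA_real_
    }
    data.frame(subject_id = tr$subject_id[1], pair_id = tr$pair_id[1],
               zygosity = tr$zygosity[1], twin = NA_integer_,
               age = tr$age[1], sex = tr$sex[1],
               n_trials_used = sum(usable),
               update_mean = upd_mean, learning_score = lscore,
               memory_score = mem, prior_mean = prior_mean,
               error_mean = err_mean,
               vividness_mean = rating_mean("vividness"),
               negativity_mean = rating_mean("negativity"),
               familiarity_mean = rating_mean("familiarity"),
               experience_mean = rating_mean("past_experience"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # twin index within pair, by subject id order
  out <- out[order(out$pair_id, out$subject_id), ]
  out$twin <- stats::ave(seq_len(nrow(out)), out$pair_id,
                         FUN = seq_along)
  attr(out, "n_excluded_equal") <- n_excluded
  out
}

#' Across-subject associations between priors and ratings
#'
#' For each rating scale (and the recalled probability), correlates each
#' subject's first estimate with that scale across their rated trials, then
#' tests the per-subject Pearson coefficients against zero with a one-sample
#' t-test.
#'
#' @param trials trial data.frame.
#' @param scales columns to associate with the first estimate.
#' @param min_trials minimum rated trials with variance per subject
#'   (default 3); degenerate subjects are skipped and counted.
#' @return data.frame with one row per scale: \code{scale}, \code{mean_r},
#'   \code{sd_r}, \code{t}, \code{df}, \code{p}, \code{n_subjects},
#'   \code{n_skipped}.
#' @export
prior_rating_associations <- function(trials,
                                      scales = c("vividness", "negativity",
                                                 "familiarity",
                                                 "past_experience",
                                                 "recalled_probability"),
                                      min_trials = 3L) {
  split_idx <- split(seq_len(nrow(trials)), trials$subject_id)
  rows <- lapply(scales, function(sc) {
    rs <- vapply(split_idx, function(idx) {
      x <- trials$first_estimate[idx]
      y <- trials[[sc]][idx]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_trials) return(NA_real_)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    used <- rs[!is.na(rs)]
    tt <- stats::t.test(used, mu = 0)
    data.frame(scale = sc, mean_r = mean(used), sd_r = stats::sd(used),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n_subjects = length(used),
               n_skipped = sum(is.na(rs)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level tests of updating and learning
#'
#' One-sample t-tests of the per-subject mean update and learning score
#' against zero (positive values indicate belief change in the direction of
#' the information, i.e. learning).
#'
#' @param phenotypes output of [subject_phenotypes()].
#' @return data.frame with rows \code{update} and \code{learning}:
#'   \code{mean}, \code{sd}, \code{t}, \code{df}, \code{p}, \code{n}.
#' @export
group_mean_tests <- function(phenotypes) {
  one <- function(v, label) {
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("need at least 2 subjects with ", label)
    if (stats::sd(v) == 0) {
      # t.test errors on constant data; t is 0/0 -> define 0 when mean is 0
      return(data.frame(phenotype = label, mean = mean(v), sd = 0,
                        t = if (mean(v) == 0) 0 else Inf * sign(mean(v)),
                        df = length(v) - 1, p = NA_real_, n = length(v),
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(v, mu = 0)
    data.frame(phenotype = label, mean = mean(v), sd = stats::sd(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(v), stringsAsFactors = FALSE)
  }
  out <- rbind(one(phenotypes$update_mean, "update"),
               one(phenotypes$learning_score, "learning"))
  rownames(out) <- NULL
  out
}

#' Long-format modelling table for external mixed-model fits
#'
#' Exports rated trials in long format (one row per subject x rated event,
#' first estimate plus the four ratings) for use with external mixed-effects
#' modelling tools; the package itself does not fit that regression.
#'
#' @param trials trial data.frame.
#' @return data.frame with columns \code{subject_id}, \code{pair_id},
#'   \code{event_id}, \code{first_estimate}, \code{familiarity},
#'   \code{past_experience}, \code{vividness}, \code{negativity}.
#' @export
modelling_table <- function(trials) {
  rated <- !is.na(trials$vividness) | !is.na(trials$negativity) |
    !is.na(trials$familiarity) | !is.na(trials$past_experience)
  out <- trials[rated, c("subject_id", "pair_id", "event_id", "first_estimate",
                         "familiarity", "past_experience", "vividness",
                         "negativity")]
  rownames(out) <- NULL
  out
}
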