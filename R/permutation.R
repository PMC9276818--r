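#' Arrange subject phenotypes as twin pairs
#'
#' Reshapes the per-subject phenotype table into one row per complete pair
#' (both members present), with phenotype columns suffixed \code{_1} /
#' \code{_2}. Incomplete or mixed-sex pairs are dropped with a message.
#'
#' @param phenotypes output of [subject_phenotypes()] (or a latent-trait table
#'   with the same identifier columns).
#' @param value_cols columns to widen; defaults to every numeric column
#'   except identifiers and demographics.
#' @return data.frame with columns \code{pair_id}, \code{zygosity},
#'   \code{age}, \code{sex} and each value column twice.
#' @export
pair_phenotypes <- function(phenotypes, value_cols = NULL) {
  id_cols <- c("subject_id", "pair_id", "zygosity", "twin", "age", "sex",
               "n_trials_used")
  if (is.null(value_cols))
    value_cols <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                                   logical(1))],
                          id_cols)
  sp <- split(phenotypes, phenotypes$pair_id)
  keep <- vapply(sp, function(d) nrow(d) == 2 && length(unique(d$sex)) == 1,
                 logical(1))
  if (any(!keep))
    message(sum(!keep), " pair(s) dropped (incomplete or mixed-sex)")
  sp <- sp[keep]
  rows <- lapply(sp, function(d) {
    d <- d[order(d$twin, d$subject_id), ]
    out <- data.frame(pair_id = d$pair_id[1], zygosity = d$zygosity[1],
                      age = d$age[1], sex = d$sex[1], stringsAsFactors = FALSE)
    for (v in value_cols) {
      out[[paste0(v, "_1")]] <- d[[v]][1]
      out[[paste0(v, "_2")]] <- d[[v]][2]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Control factors for a phenotype
#'
#' The covariate set used when assessing twin similarity for a phenotype:
#' first estimate (prior), familiarity, past experience, vividness,
#' negativity and memory, minus the focal phenotype itself; estimation error
#' is added for the update phenotype, and memory is omitted for the prior
#' (the first estimate is given before the information is revealed, so memory
#' cannot influence it).
#'
#' @param phenotype one of \code{"update"}, \code{"learning"},
#'   \code{"memory"}, \code{"prior"}, \code{"vividness"},
#'   \code{"negativity"}, \code{"familiarity"}, \code{"experience"}.
#' @return character vector of control-factor names.
#' @export
control_factors <- function(phenotype) {
  phenotype <- match.arg(phenotype, names(.phenotype_cols))
  base <- c("prior", "familiarity", "experience", "vividness", "negativity",
            "memory")
  if (phenotype == "update") base <- c(base, "error")
  if (phenotype == "prior") base <- setdiff(base, "memory")
  setdiff(base, phenotype)
}

#' Pair-level covariates for a given A/B assignment
#'
#' For each control factor the covariate is the difference of subject means,
#' twin A minus twin B, under the supplied assignment. Age is entered as the
#' pair-level value (twins share one age, so a within-pair difference would be
#' identically zero and could not control for age).
#'
#' @param pairs output of [pair_phenotypes()].
#' @param phenotype focal phenotype name (see [control_factors()]).
#' @param covariates control-factor names; default [control_factors()].
#' @param assignment logical vector, one per pair: \code{TRUE} means member 2
#'   is labelled twin A.
#' @param include_age add the pair-level age column (default \code{TRUE}).
#' @return numeric matrix, one row per pair.
#' @export
build_pair_covariates <- function(pairs, phenotype,
                                  covariates = control_factors(phenotype),
                                  assignment = rep(FALSE, nrow(pairs)),
                                  include_age = TRUE) {
  stopifnot(length(assignment) == nrow(pairs))
  s <- ifelse(assignment, -1, 1)
  cols <- lapply(covariates, function(f) {
    col <- .phenotype_cols[[f]]
    s * (pairs[[paste0(col, "_1")]] - pairs[[paste0(col, "_2")]])
  })
  Z <- do.call(cbind, c(cols, if (include_age) list(pairs$age)))
  if (is.null(Z)) Z <- matrix(numeric(0), nrow(pairs), 0)
  colnames(Z) <- c(if (length(covariates)) paste0("diff_", covariates),
                   if (include_age) "age")
  Z
}

#' Partial correlation
#'
#' Product-moment correlation of the residuals of \code{x} and \code{y} after
#' least-squares projection onto \code{Z} plus an intercept. With no
#' covariates this reduces to the plain correlation. Collinear columns of
#' \code{Z} are dropped with a warning.
#'
#' @param x,y numeric vectors.
#' @param Z covariate matrix (or \code{NULL} for none).
#' @return correlation in [-1, 1].
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(stats::cor(x, y))
  Z <- as.matrix(Z)
  if (length(x) < ncol(Z) + 3)
    stop("need at least ncol(Z) + 3 observations for a partial correlation")
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient covariate matrix; dropping collinear columns")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, cbind(x, y))
  stats::cor(res[, 1], res[, 2])
}

#' Twin similarity by permutation partial correlation
#'
#' Because labelling the members of a pair as "twin A" and "twin B" is
#' arbitrary but affects the correlation, each pair's labels are flipped
#' independently with probability 1/2 on each of \code{n_perm} permutations;
#' each permutation yields a partial correlation between the twin-A and
#' twin-B phenotype vectors (controlling for the between-twin differences of
#' the control factors and for pair-level age), separately for MZ and DZ
#' pairs. The mean and the 2.5/97.5 percentiles of the resulting distribution
#' summarize twin similarity per zygosity.
#'
#' Pairs with a missing phenotype or control factor for either member are
#' dropped listwise for that phenotype only.
#'
#' @param pairs output of [pair_phenotypes()].
#' @param phenotype focal phenotype name.
#' @param covariates control-factor names (default [control_factors()];
#'   use \code{character(0)} for an unadjusted correlation).
#' @param n_perm number of random A/B reassignments (default 10000).
#' @param seed integer seed.
#' @param include_age include pair-level age as a covariate.
#' @param exhaustive enumerate all \code{2^n_pairs} assignments instead of
#'   Monte-Carlo sampling (requires <= 20 usable pairs in each zygosity).
#' @param keep_distribution store the full vector of permuted correlations.
#' @return object of class \code{twin_permutation}: a list with one element
#'   per zygosity, each containing \code{mean_r}, \code{q2.5}, \code{q97.5},
#'   \code{n_pairs}, \code{n_perm}, \code{n_dropped} and (optionally)
#'   \code{r}.
#' @export
permutation_twin_correlation <- function(pairs, phenotype,
                                         covariates = control_factors(phenotype),
                                         n_perm = 10000L, seed = 1L,
                                         include_age = TRUE,
                                         exhaustive = FALSE,
                                         keep_distribution = TRUE) {
  phenotype <- match.arg(phenotype, names(.phenotype_cols))
  pcol <- .phenotype_cols[[phenotype]]
  set.seed(seed)
  zygs <- intersect(c("MZ", "DZ"), unique(pairs$zygosity))
  out <- lapply(zygs, function(z) {
    pz <- pairs[pairs$zygosity == z, , drop = FALSE]
    need <- c(paste0(pcol, c("_1", "_2")),
              as.vector(outer(.phenotype_cols[covariates], c("_1", "_2"),
                              paste0)))
    complete <- stats::complete.cases(pz[, need, drop = FALSE])
    n_dropped <- sum(!complete)
    pz <- pz[complete, , drop = FALSE]
    np <- nrow(pz)
    if (np < 10)
      stop("fewer than 10 usable ", z, " pairs for phenotype '", phenotype, "'")
    p1 <- pz[[paste0(pcol, "_1")]]
    p2 <- pz[[paste0(pcol, "_2")]]
    Z0 <- build_pair_covariates(pz, phenotype, covariates,
                                assignment = rep(FALSE, np),
                                include_age = include_age)
    diff_cols <- grep("^diff_", colnames(Z0))

    flips <- if (exhaustive) {
      if (np > 20) stop("exhaustive enumeration limited to 20 pairs")
      m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), np)))
      dimnames(m) <- NULL
      m
    } else {
      matrix(stats::runif(n_perm * np) < 0.5, nrow = n_perm)
    }
    r <- vapply(seq_len(nrow(flips)), function(b) {
      f <- flips[b, ]
      s <- ifelse(f, -1, 1)
      x <- ifelse(f, p2, p1)
      y <- ifelse(f, p1, p2)
      Z <- Z0
      if (length(diff_cols))
        Z[, diff_cols] <- Z0[, diff_cols, drop = FALSE] * s
      suppressWarnings(partial_correlation(x, y, Z))
    }, numeric(1))
    res <- list(zygosity = z, phenotype = phenotype,
                mean_r = mean(r),
                q2.5 = unname(stats::quantile(r, 0.025)),
                q97.5 = unname(stats::quantile(r, 0.975)),
                n_pairs = np, n_perm = nrow(flips), n_dropped = n_dropped,
                covariates = covariates, include_age = include_age,
                seed = seed)
    if (keep_distribution) res$r <- r
    res
  })
  names(out) <- zygs
  structure(out, class = "twin_permutation", phenotype = phenotype)
}

#' @export
print.twin_permutation <- function(x, ...) {
  cat(sprintf("Permutation twin correlations: phenotype '%s'\n",
              attr(x, "phenotype")))
  for (z in names(x)) {
    r <- x[[z]]
    cat(sprintf("  %s: mean r = %.3f (2.5%%/97.5%% = %.3f/%.3f), %d pairs, %d permutations\n",
                z, r$mean_r, r$q2.5, r$q97.5, r$n_pairs, r$n_perm))
  }
  invisible(x)
}

#' Overlap of MZ and DZ permutation percentile intervals
#'
#' Tests whether the [2.5, 97.5] percentile intervals of the MZ and DZ
#' permutation distributions intersect, and which mean correlation is larger.
#' Non-overlap with the MZ interval above the DZ interval indicates greater
#' similarity of MZ twins, the signature of heritability.
#'
#' @param mz,dz either a single \code{twin_permutation} object (containing
#'   both zygosities) passed as \code{mz}, or two length-2 numeric intervals
#'   \code{c(lower, upper)}.
#' @return list with \code{overlap} (logical), \code{larger} ("MZ"/"DZ"),
#'   and the two intervals.
#' @export
interval_overlap <- function(mz, dz = NULL) {
  if (inherits(mz, "twin_permutation")) {
    stopifnot(all(c("MZ", "DZ") %in% names(mz)))
    int_mz <- c(mz$MZ$q2.5, mz$MZ$q97.5)
    int_dz <- c(mz$DZ$q2.5, mz$DZ$q97.5)
  } else {
    int_mz <- mz; int_dz <- dz
  }
  stopifnot(length(int_mz) == 2, length(int_dz) == 2)
  overlap <- int_mz[1] <= int_dz[2] && int_dz[1] <= int_mz[2]
  larger <- if (mean(int_mz) >= mean(int_dz)) "MZ" else "DZ"
  list(overlap = overlap, larger = larger,
       mz_interval = int_mz, dz_interval = int_dz)
}
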