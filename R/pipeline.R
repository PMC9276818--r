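#' Configuration for an end-to-end analysis run
#'
#' Bundles the inputs of [run_twin_pipeline()]: either a simulation
#' configuration or a trial-level CSV path, the phenotypes to analyse, the
#' permutation and model-fitting settings, and the output directory. One
#' master seed streams per-stage sub-seeds (simulation, permutation,
#' optimizer restarts) so each stage is independently reproducible.
#'
#' Phenotype-specific covariate exclusions are enforced by
#' [control_factors()] / [default_biometric_covariates()]: memory is never a
#' control for the prior, and estimation error is added for update.
#'
#' @param simulation a [twin_sim_config()] (ignored when \code{input_csv} is
#'   given).
#' @param input_csv optional path to a trial-level CSV.
#' @param phenotypes phenotypes to analyse.
#' @param n_perm permutations per phenotype and zygosity.
#' @param models candidate biometric models.
#' @param use_covariates control for the phenotype-specific covariate sets
#'   (\code{FALSE} gives the unadjusted analysis).
#' @param memory_tolerance recall match tolerance.
#' @param seed master seed.
#' @param output_dir directory for the report bundle (created if needed);
#'   \code{NULL} suppresses file output.
#' @param event_subsets optional named list of event-id vectors for
#'   stratified fits of the prior phenotype.
#' @return object of class \code{twin_run_config}.
#' @export
twin_run_config <- function(simulation = twin_sim_config(),
                            input_csv = NULL,
                            phenotypes = c("update", "learning", "memory",
                                           "vividness", "negativity", "prior"),
                            n_perm = 10000L,
                            models = c("ACE", "ADE", "AE", "CE", "E"),
                            use_covariates = TRUE,
                            memory_tolerance = 0,
                            seed = 1L,
                            output_dir = NULL,
                            event_subsets = NULL) {
  phenotypes <- match.arg(phenotypes, names(.phenotype_cols),
                          several.ok = TRUE)
  structure(list(simulation = simulation, input_csv = input_csv,
                 phenotypes = phenotypes, n_perm = as.integer(n_perm),
                 models = models, use_covariates = isTRUE(use_covariates),
                 memory_tolerance = memory_tolerance,
                 seed = as.integer(seed), output_dir = output_dir,
                 event_subsets = event_subsets),
            class = "twin_run_config")
}

.stage_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full twin analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-subject phenotypes -> permutation
#' twin correlations -> biometric model comparison into one deterministic,
#' seeded run, with a log accounting for every subject and pair dropped at
#' each stage. When \code{config$output_dir} is set, writes
#' \code{phenotypes.csv}, \code{permutation.json}, \code{biometric.csv} (a
#' per-phenotype, per-model table with the AIC winner flagged) and
#' \code{log.txt} with a provenance header (package version, seed, config
#' hash).
#'
#' @param config a [twin_run_config()].
#' @return (invisibly) a list with \code{trials}, \code{phenotypes},
#'   \code{permutation} (per phenotype), \code{selection} (per phenotype),
#'   \code{stratified} (if requested), \code{biometric_table} and \code{log}.
#' @export
run_twin_pipeline <- function(config) {
  stopifnot(inherits(config, "twin_run_config"))
  n_ph <- length(config$phenotypes)
  seeds <- .stage_seeds(config$seed, 2L + 2L * n_ph)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  cfg_json <- jsonlite::toJSON(unclass(config)[c("phenotypes", "n_perm",
                                                 "models", "use_covariates",
                                                 "memory_tolerance", "seed")],
                               auto_unbox = TRUE)
  cfg_hash <- sprintf("%08x", sum(as.integer(charToRaw(as.character(cfg_json))) *
                                    seq_along(charToRaw(as.character(cfg_json)))) %%
                        .Machine$integer.max)
  say("twinbelief %s | master seed %d | config hash %s",
      as.character(utils::packageVersion("twinbelief")), config$seed, cfg_hash)

  # stage 1: obtain trials
  if (!is.null(config$input_csv)) {
    trials <- read_trial_csv(config$input_csv)
    say("stage simulate: loaded %d trial rows from %s", nrow(trials),
        config$input_csv)
  } else {
    sim <- config$simulation
    sim$seed <- seeds[1]
    trials <- simulate_task_trials(simulate_latent_traits(sim), sim)
    say("stage simulate: generated %d trial rows (%d MZ + %d DZ pairs)",
        nrow(trials), sim$n_mz_pairs, sim$n_dz_pairs)
  }

  # stage 2: phenotypes
  phen <- subject_phenotypes(trials,
                             memory_tolerance = config$memory_tolerance)
  say("stage metrics: %d subjects; %d trials excluded (first == information)",
      nrow(phen), attr(phen, "n_excluded_equal"))
  pairs <- suppressMessages(pair_phenotypes(phen))
  say("stage metrics: %d complete pairs (%d subjects unpaired or dropped)",
      nrow(pairs), nrow(phen) - 2L * nrow(pairs))

  # stage 3: permutation twin correlations
  permutation <- list()
  for (i in seq_len(n_ph)) {
    ph <- config$phenotypes[i]
    covs <- if (config$use_covariates) control_factors(ph) else character(0)
    res <- permutation_twin_correlation(pairs, ph, covariates = covs,
                                        n_perm = config$n_perm,
                                        seed = seeds[2L + i],
                                        include_age = config$use_covariates,
                                        keep_distribution = FALSE)
    permutation[[ph]] <- res
    for (z in names(res))
      say("stage twincorr [%s/%s]: mean r %.3f [%.3f, %.3f], %d pairs used, %d dropped",
          ph, z, res[[z]]$mean_r, res[[z]]$q2.5, res[[z]]$q97.5,
          res[[z]]$n_pairs, res[[z]]$n_dropped)
  }

  # stage 4: biometric model comparison
  selection <- list()
  for (i in seq_len(n_ph)) {
    ph <- config$phenotypes[i]
    covs <- if (config$use_covariates) default_biometric_covariates(ph)
            else NULL
    sel <- suppressMessages(
      model_selection(pairs, ph, models = config$models, covariates = covs,
                      seed = seeds[2L + n_ph + i]))
    selection[[ph]] <- sel
    say("stage biometric [%s]: winner %s (AIC %.3f), %d pairs used", ph,
        sel$winner, sel$table$AIC[1], sel$fits[[sel$winner]]$n_pairs)
  }
  biometric_table <- do.call(rbind, lapply(names(selection), function(ph) {
    tb <- selection[[ph]]$table
    cbind(phenotype = ph, tb)
  }))

  # optional: stratified fits of the prior phenotype by event subset
  stratified <- NULL
  if (!is.null(config$event_subsets)) {
    covs <- if (config$use_covariates)
      default_biometric_covariates("prior") else NULL
    stratified <- stratified_fit(trials, config$event_subsets, "prior",
                                 model = "AE", covariates = covs)
    for (nm in names(stratified))
      say("stage stratified [prior/%s]: A = %.1f%%", nm,
          stratified[[nm]]$standardized["A"])
  }

  out <- list(trials = trials, phenotypes = phen, pairs = pairs,
              permutation = permutation, selection = selection,
              stratified = stratified, biometric_table = biometric_table,
              log = log, config = config)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(phen, file.path(config$output_dir, "phenotypes.csv"),
                     row.names = FALSE, na = "")
    perm_json <- lapply(permutation, function(res)
      lapply(res, function(r) r[c("mean_r", "q2.5", "q97.5", "n_pairs",
                                  "n_perm", "n_dropped", "covariates")]))
    jsonlite::write_json(perm_json,
                         file.path(config$output_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(biometric_table,
                     file.path(config$output_dir, "biometric.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$output_dir, "log.txt"))
  }
  invisible(out)
}

#' Run the analysis with and without covariate adjustment
#'
#' Runs the permutation twin correlations and the biometric model comparison
#' twice — once controlling for the phenotype-specific covariate sets and
#' once fully unadjusted — and returns a side-by-side table. The study's
#' conclusion should not hinge on the adjustment.
#'
#' @param config a [twin_run_config()]; its \code{use_covariates} field is
#'   overridden for each arm.
#' @return list with \code{adjusted}, \code{unadjusted} (full pipeline
#'   results) and \code{comparison}, a data.frame with one row per phenotype
#'   holding the mean MZ/DZ permuted correlations, the AIC-winning model and
#'   the AE-model additive estimate for each arm.
#' @export
compare_covariate_adjustment <- function(config) {
  stopifnot(inherits(config, "twin_run_config"))
  arm <- function(use) {
    cfg <- config; cfg$use_covariates <- use; cfg$output_dir <- NULL
    run_twin_pipeline(cfg)
  }
  adjusted <- arm(TRUE)
  unadjusted <- arm(FALSE)
  row_of <- function(res, ph) {
    ae <- res$selection[[ph]]$fits[["AE"]]
    c(r_mz = res$permutation[[ph]]$MZ$mean_r,
      r_dz = res$permutation[[ph]]$DZ$mean_r,
      a_ae = if (!is.null(ae)) unname(ae$standardized["A"]) else NA_real_)
  }
  comparison <- do.call(rbind, lapply(config$phenotypes, function(ph) {
    a <- row_of(adjusted, ph); u <- row_of(unadjusted, ph)
    data.frame(phenotype = ph,
               r_mz_adj = a["r_mz"], r_dz_adj = a["r_dz"],
               a_pct_adj = a["a_ae"],
               winner_adj = adjusted$selection[[ph]]$winner,
               r_mz_unadj = u["r_mz"], r_dz_unadj = u["r_dz"],
               a_pct_unadj = u["a_ae"],
               winner_unadj = unadjusted$selection[[ph]]$winner,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(adjusted = adjusted, unadjusted = unadjusted, comparison = comparison)
}
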