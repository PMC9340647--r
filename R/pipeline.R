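#' Load a run configuration from YAML
#'
#' A run configuration collects the analysis settings in one validated
#' object: where the trial data comes from (a CSV path or a synthetic
#' generator block), the economic parameter overrides, the model options
#' (horizon, peak weeks, observed-distribution flag) and the sensitivity
#' options (PSA draws, seed, willingness-to-pay grid).
#'
#' Unknown fields are rejected with their path so configuration typos fail
#' before any computation starts.
#'
#' @param path Path to a YAML file. Recognized top-level blocks: `input_csv`
#'   (string) or `generator` (field overrides for [generator_config()]),
#'   `econ` (overrides for [econ_params()]), `model`
#'   (`horizon_weeks`, `peak_weeks`, `use_observed_distributions`),
#'   `sensitivity` (`owsa`, `psa_draws`, `seed`, `lambda_max`,
#'   `lambda_step`, `horizon_grid`).
#' @return Object of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("input_csv", "generator", "econ", "model", "sensitivity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model_known <- c("horizon_weeks", "peak_weeks",
                   "use_observed_distributions")
  sens_known <- c("owsa", "psa_draws", "seed", "lambda_max", "lambda_step",
                  "horizon_grid")
  for (blk in list(c("model", model_known), c("sensitivity", sens_known))) {
    bad <- setdiff(names(raw[[blk[1]]]), blk[-1])
    if (length(bad) > 0) {
      stop("unknown field(s) in '", blk[1], "': ",
           paste(paste0(blk[1], ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  cfg <- list(
    input_csv = raw$input_csv,
    generator = if (is.null(raw$input_csv)) {
      do.call(generator_config, raw$generator %||% list())
    },
    econ = do.call(econ_params, raw$econ %||% list()),
    horizon_weeks = raw$model$horizon_weeks %||% 260,
    peak_weeks = raw$model$peak_weeks %||% 11,
    use_observed_distributions =
      isTRUE(raw$model$use_observed_distributions),
    owsa = !isFALSE(raw$sensitivity$owsa),
    psa_draws = raw$sensitivity$psa_draws %||% 1000,
    seed = raw$sensitivity$seed %||% 1,
    lambda_grid = seq(0, raw$sensitivity$lambda_max %||% 100000,
                      by = raw$sensitivity$lambda_step %||% 2500),
    horizon_grid = raw$sensitivity$horizon_grid %||%
      c(48, 104, 156, 208, 260)
  )
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit both regressions and build a model context from trial data
#'
#' Convenience wrapper for the estimation half of the pipeline: LOCF
#' imputation, design construction, the ordered-probit transition fit, the
#' hospitalization probit, and the pooled empirical baseline state mix
#' (baseline is randomized, so arms share it).
#'
#' The state-linked absenteeism fractions are estimated from the trial's
#' work-productivity observations (mean fraction among patients concurrently
#' in each state); states never observed with an absenteeism measure keep
#' the configured default.
#'
#' @param trial Trial table (e.g. from [read_trial_csv()] or
#'   [generate_trial()]).
#' @param params An `econ_params`.
#' @param peak_weeks,horizon_weeks Model settings.
#' @return A [cea_context()] with attributes `design` and `excluded`.
#' @export
fit_cea_context <- function(trial, params = econ_params(), peak_weeks = 11,
                            horizon_weeks = 260) {
  imp <- impute_locf(trial)
  design <- build_design(imp$data, peak_weeks)
  fit <- fit_ordered_probit(design)
  hfit <- fit_hosp_probit(design)
  obs <- imp$data[!is.na(imp$data$absenteeism_frac), , drop = FALSE]
  if (nrow(obs) > 0) {
    st <- state_code(state_from_cdai(obs$cdai))
    for (s in unique(st)) {
      params$absenteeism_frac_by_state[s] <-
        mean(obs$absenteeism_frac[st == s])
    }
  }
  base_states <- state_code(state_from_cdai(
    imp$data$cdai[imp$data$week == 0]))
  baseline <- tabulate(base_states, N_STATES) / length(base_states)
  visit_weeks <- sort(unique(imp$data$week))
  ctx <- cea_context(fit, hfit, baseline, params, visit_weeks, peak_weeks,
                     horizon_weeks)
  attr(ctx, "design") <- design
  attr(ctx, "excluded") <- imp$excluded
  ctx
}

#' Run the complete analysis and write results to a directory
#'
#' End-to-end orchestration: obtain the trial table (from CSV or the
#' synthetic generator), fit the transition and hospitalization models, run
#' both cohort arms, evaluate the cost-utility comparison, and (optionally)
#' the one-way sensitivity analysis, time-horizon sweep, probabilistic
#' sensitivity analysis and acceptability curves. All outputs are plain CSV
#' or JSON files under `out_dir`, together with a run manifest recording the
#' seed and package version; nothing mutates the inputs.
#'
#' @param config A `run_config` ([load_run_config()]) or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   file output.
#' @return List: `trial`, `context`, `result` (a `cea_result`), `owsa`,
#'   `horizon`, `psa`, `ceac`.
#' @export
run_full_analysis <- function(config = NULL, out_dir = NULL) {
  if (is.null(config)) {
    config <- structure(list(
      input_csv = NULL, generator = generator_config(),
      econ = econ_params(), horizon_weeks = 260, peak_weeks = 11,
      use_observed_distributions = FALSE, owsa = TRUE, psa_draws = 1000,
      seed = 1, lambda_grid = seq(0, 100000, by = 2500),
      horizon_grid = c(48, 104, 156, 208, 260)), class = "run_config")
  }
  trial <- if (!is.null(config$input_csv)) {
    read_trial_csv(config$input_csv)
  } else {
    generate_trial(config$generator, seed = config$seed)
  }
  ctx <- fit_cea_context(trial, config$econ, config$peak_weeks,
                         config$horizon_weeks)
  visit_dists <- NULL
  if (config$use_observed_distributions) {
    imp <- impute_locf(trial)$data
    result <- {
      tr_tc <- run_cohort(ctx$fit, ctx$hfit, "TC", ctx$baseline,
                          ctx$visit_weeks, ctx$horizon_weeks,
                          ctx$peak_weeks,
                          empirical_visit_distributions(imp, "TC",
                                                        ctx$visit_weeks))
      tr_cm <- run_cohort(ctx$fit, ctx$hfit, "CM", ctx$baseline,
                          ctx$visit_weeks, ctx$horizon_weeks,
                          ctx$peak_weeks,
                          empirical_visit_distributions(imp, "CM",
                                                        ctx$visit_weeks))
      evaluate_cea(tr_tc, tr_cm, config$econ)
    }
  } else {
    result <- evaluate_context(ctx)
  }
  owsa <- if (config$owsa) run_owsa(ctx) else NULL
  horizon <- horizon_sweep(ctx, config$horizon_grid)
  psa <- if (config$psa_draws > 0) {
    run_psa(ctx, n_draws = config$psa_draws, seed = config$seed)
  } else NULL
  curve <- if (!is.null(psa)) ceac(psa, config$lambda_grid) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trial, file.path(out_dir, "trial.csv"),
                     row.names = FALSE)
    write_fit_json(ctx$fit, file.path(out_dir, "transition_fit.json"))
    write_fit_json(ctx$hfit, file.path(out_dir, "hosp_fit.json"))
    write_cea_json(result, file.path(out_dir, "cea_result.json"))
    if (!is.null(owsa)) {
      utils::write.csv(owsa, file.path(out_dir, "owsa.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(horizon, file.path(out_dir, "horizon.csv"),
                     row.names = FALSE)
    if (!is.null(psa)) {
      utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                       row.names = FALSE)
      utils::write.csv(curve, file.path(out_dir, "ceac.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      seed = config$seed,
      horizon_weeks = config$horizon_weeks,
      psa_draws = config$psa_draws,
      package_version = as.character(utils::packageVersion("crohncea")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(trial = trial, context = ctx, result = result, owsa = owsa,
       horizon = horizon, psa = psa, ceac = curve)
}
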