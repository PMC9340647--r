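#' Bundle the fitted models and settings needed to re-run the pipeline
#'
#' A model context packages everything the deterministic and probabilistic
#' sensitivity analyses need to re-evaluate the cohort model from scratch:
#' the two fitted regressions, the baseline state mix, schedule, horizon and
#' economic parameters.
#'
#' @param fit A `transition_fit`.
#' @param hfit A `hosp_fit` (or `NULL` for a zero hospitalization toll).
#' @param baseline Length-4 baseline state distribution.
#' @param params An `econ_params`.
#' @param visit_weeks,peak_weeks,horizon_weeks Model schedule settings.
#' @return Object of class `cea_context`.
#' @export
cea_context <- function(fit, hfit, baseline, params = econ_params(),
                        visit_weeks = c(0, 2, 6, 11, 23, 35, 48),
                        peak_weeks = 11, horizon_weeks = 260) {
  structure(list(fit = fit, hfit = hfit, baseline = baseline,
                 params = params, visit_weeks = visit_weeks,
                 peak_weeks = peak_weeks, horizon_weeks = horizon_weeks),
            class = "cea_context")
}

# run both arms and evaluate; any element of the context can be overridden
evaluate_context <- function(ctx, params = ctx$params,
                             fit = ctx$fit, hfit = ctx$hfit,
                             baseline = ctx$baseline,
                             horizon_weeks = ctx$horizon_weeks) {
  tr_tc <- run_cohort(fit, hfit, "TC", baseline, ctx$visit_weeks,
                      horizon_weeks, ctx$peak_weeks)
  tr_cm <- run_cohort(fit, hfit, "CM", baseline, ctx$visit_weeks,
                      horizon_weeks, ctx$peak_weeks)
  evaluate_cea(tr_tc, tr_cm, params)
}

# ICER-or-signed-surrogate used for tornado ordering: under dominance the
# ratio delta_cost/delta_qaly is still well defined numerically
raw_icer <- function(res, include_absenteeism = FALSE) {
  inc <- if (include_absenteeism) res$with_absenteeism else res$direct
  if (inc$delta_qaly == 0) return(NA_real_)
  inc$delta_cost / inc$delta_qaly
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each parameter alone to the low then the high end of its declared
#' range, holding everything else at base, and records the resulting ICER.
#' Single-valued alternatives (e.g. the SF-6D utility set) produce one-sided
#' bars. Results are sorted by bar extent, the tornado order.
#'
#' @param ctx A [cea_context()]. Ranges are taken from `ctx$params$ranges`;
#'   the special entries `baseline_moderate_pct` (re-runs the cohort model
#'   with the baseline moderate share moved and the severe/very-severe
#'   remainder rescaled) and `utility_source` (one-sided swap) are handled
#'   structurally.
#' @param include_absenteeism Use the absenteeism-inclusive totals.
#' @return `data.frame` (parameter, low, high, icer_low, icer_high, extent),
#'   sorted by decreasing extent, with the base ICER in
#'   `attr(, "base_icer")`.
#' @export
run_owsa <- function(ctx, include_absenteeism = FALSE) {
  stopifnot(inherits(ctx, "cea_context"))
  base_res <- evaluate_context(ctx)
  base_icer <- raw_icer(base_res, include_absenteeism)
  eval_at <- function(name, value) {
    params <- ctx$params
    if (name == "utility_source") {
      params$utility_source <- value
      return(raw_icer(evaluate_context(ctx, params = params),
                      include_absenteeism))
    }
    if (name == "baseline_moderate_pct") {
      pool <- ctx$baseline[3] + ctx$baseline[4]
      split <- if (pool > 0) ctx$baseline[3:4] / pool else c(0.5, 0.5)
      mod <- value / 100
      baseline <- c(ctx$baseline[1], 0, 0, 0)
      baseline[2] <- mod * (1 - ctx$baseline[1])
      rest <- (1 - ctx$baseline[1]) * (1 - mod)
      baseline[3:4] <- rest * split
      return(raw_icer(evaluate_context(ctx, baseline = baseline),
                      include_absenteeism))
    }
    params[[name]] <- value
    raw_icer(evaluate_context(ctx, params = validate_econ_params(params)),
             include_absenteeism)
  }
  rows <- lapply(names(ctx$params$ranges), function(name) {
    rg <- ctx$params$ranges[[name]]
    if (is.numeric(rg) && length(rg) == 2L) {
      if (rg[1] > rg[2]) stop("inverted range for ", name, call. = FALSE)
      lo <- eval_at(name, rg[1])
      hi <- eval_at(name, rg[2])
      data.frame(parameter = name, low = rg[1], high = rg[2],
                 icer_low = lo, icer_high = hi,
                 extent = max(abs(c(lo, hi) - base_icer)),
                 stringsAsFactors = FALSE)
    } else {
      # one-sided alternative value
      alt <- eval_at(name, rg[[1]])
      data.frame(parameter = name, low = NA_real_, high = NA_real_,
                 icer_low = alt, icer_high = NA_real_,
                 extent = abs(alt - base_icer), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$extent), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' ICER as a function of the model time horizon
#'
#' Re-runs the full pipeline at each horizon on the grid.
#'
#' @param ctx A [cea_context()].
#' @param weeks_grid Horizons in weeks, each at least the last visit week.
#' @return `data.frame` (horizon_weeks, icer, label).
#' @export
horizon_sweep <- function(ctx, weeks_grid = c(48, 104, 156, 208, 260)) {
  rows <- lapply(weeks_grid, function(h) {
    res <- evaluate_context(ctx, horizon_weeks = h)
    data.frame(horizon_weeks = h, icer = raw_icer(res),
               label = res$direct$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Cholesky factor tolerant of positive semi-definite input; jitters once
chol_psd <- function(cov) {
  tryCatch(chol(cov), error = function(e) {
    warning("covariance not positive definite; adding 1e-10 jitter",
            call. = FALSE)
    tryCatch(chol(cov + diag(1e-10, nrow(cov))),
             error = function(e2) stop("covariance matrix is not usable: ",
                                       conditionMessage(e2), call. = FALSE))
  })
}

#' Draw correlated coefficient vectors from a fitted model
#'
#' Samples `mean + t(L) %*% z` with `L` the upper Cholesky factor of the
#' joint coefficient covariance and `z` standard normal, the standard
#' treatment of correlated regression inputs in probabilistic sensitivity
#' analysis. For ordered-probit fits, draws whose thresholds are not
#' strictly increasing are rejected and redrawn.
#'
#' @param fit A `transition_fit` or `hosp_fit`.
#' @param n Number of draws.
#' @param max_reject Safety cap on rejection rounds.
#' @return `n` x d matrix of parameter draws (columns named; for a
#'   `transition_fit`, `beta` then `tau`).
#' @export
draw_correlated_coefficients <- function(fit, n = 1, max_reject = 1000) {
  mean_vec <- if (inherits(fit, "transition_fit")) c(fit$beta, tau = fit$tau)
    else fit$gamma
  d <- length(mean_vec)
  if (all(fit$cov == 0)) {
    out <- matrix(rep(mean_vec, each = n), n, d)
    colnames(out) <- names(mean_vec)
    return(out)
  }
  L <- chol_psd(fit$cov)
  draw_block <- function(m) {
    z <- matrix(stats::rnorm(m * d), m, d)
    sweep(z %*% L, 2, mean_vec, "+")
  }
  out <- draw_block(n)
  if (inherits(fit, "transition_fit")) {
    tau_idx <- length(fit$beta) + seq_along(fit$tau)
    bad <- function(m) apply(m[, tau_idx, drop = FALSE], 1,
                             function(t) any(diff(t) <= 0))
    rejected <- 0L
    repeat {
      b <- which(bad(out))
      if (length(b) == 0L) break
      rejected <- rejected + length(b)
      if (rejected > max_reject) {
        stop("too many threshold-ordering rejections", call. = FALSE)
      }
      out[b, ] <- draw_block(length(b))
    }
    if (rejected > 0L) {
      message(rejected, " draw(s) rejected for threshold ordering")
    }
  }
  colnames(out) <- names(mean_vec)
  out
}

# gamma draw matched to mean and coefficient of variation (cv = 0 -> mean)
rgamma_cv <- function(n, mean, cv) {
  if (cv <= 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

# beta draw matched to mean and cv, clamped to a feasible variance
rbeta_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  v <- min((cv * mean)^2, 0.95 * mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo over the model parameters: regression
#' coefficients are drawn with their estimated correlation via the Cholesky
#' factor of each fit's covariance ([draw_correlated_coefficients()]); unit
#' costs and wages are drawn from gamma distributions and state utilities
#' from beta distributions, each matched to the base mean and a configurable
#' coefficient of variation (the distribution families and CVs are modelling
#' choices). Each draw re-runs the full cohort pipeline and stores the
#' incremental costs and QALYs.
#'
#' @param ctx A [cea_context()].
#' @param n_draws Number of simulations (default 1,000).
#' @param seed Integer seed; same seed, same draw table.
#' @param cost_cv,utility_cv Coefficients of variation for the gamma cost
#'   and beta utility draws (default 0.2; set to 0 to switch them off).
#' @param coef_uncertainty Draw regression coefficients from their
#'   covariance (`TRUE`) or hold them at the estimates (`FALSE`).
#' @return Object of class `psa_draws`: `draws` (a `data.frame` with one row
#'   per simulation: `delta_cost_direct`, `delta_cost_with_absenteeism`,
#'   `delta_qaly`), plus `n_draws` and `seed`.
#' @export
run_psa <- function(ctx, n_draws = 1000, seed = 1, cost_cv = 0.2,
                    utility_cv = 0.2, coef_uncertainty = TRUE) {
  stopifnot(inherits(ctx, "cea_context"), n_draws >= 1)
  set.seed(seed)
  fit0 <- ctx$fit
  hfit0 <- ctx$hfit
  coef_draws <- if (coef_uncertainty) {
    draw_correlated_coefficients(fit0, n_draws)
  } else NULL
  hosp_draws <- if (coef_uncertainty && !is.null(hfit0)) {
    draw_correlated_coefficients(hfit0, n_draws)
  } else NULL
  p0 <- ctx$params
  cost_names <- c("hosp_cost_per_admission", "fcp_test", "crp_test",
                  "adalimumab_per_40mg", "hourly_wage")
  cost_tab <- vapply(cost_names,
                     function(nm) rgamma_cv(n_draws, p0[[nm]], cost_cv),
                     numeric(n_draws))
  if (n_draws == 1L) cost_tab <- matrix(cost_tab, 1L,
                                        dimnames = list(NULL, cost_names))
  other_scale <- rgamma_cv(n_draws, 1, cost_cv)
  util0 <- active_utilities(p0)
  util_tab <- vapply(seq_len(N_STATES),
                     function(s) rbeta_cv(n_draws, util0[s], utility_cv),
                     numeric(n_draws))
  if (n_draws == 1L) util_tab <- matrix(util_tab, 1L)
  absent_tab <- vapply(seq_len(N_STATES), function(s) {
    rbeta_cv(n_draws, p0$absenteeism_frac_by_state[s], utility_cv)
  }, numeric(n_draws))
  if (n_draws == 1L) absent_tab <- matrix(absent_tab, 1L)
  n_beta <- length(fit0$beta)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    fit_i <- if (is.null(coef_draws)) fit0 else {
      transition_fit(beta = coef_draws[i, seq_len(n_beta)],
                     tau = coef_draws[i, n_beta + seq_along(fit0$tau)],
                     collapsed = fit0$collapsed)
    }
    hfit_i <- if (is.null(hfit0)) NULL
      else if (is.null(hosp_draws)) hfit0
      else hosp_fit(hosp_draws[i, ], gap_ref = hfit0$gap_ref)
    params_i <- p0
    for (nm in cost_names) params_i[[nm]] <- unname(cost_tab[i, nm])
    params_i$other_direct_weekly_by_state <-
      p0$other_direct_weekly_by_state * other_scale[i]
    if (p0$utility_source == "sf6d") {
      params_i$utility_sf6d_by_state[] <- util_tab[i, ]
    } else {
      params_i$utility_eq5d_by_state[] <- util_tab[i, ]
    }
    params_i$absenteeism_frac_by_state[] <- absent_tab[i, ]
    res <- evaluate_context(ctx, params = params_i, fit = fit_i,
                            hfit = hfit_i)
    rows[[i]] <- data.frame(
      draw = i,
      delta_cost_direct = res$direct$delta_cost,
      delta_cost_with_absenteeism = res$with_absenteeism$delta_cost,
      delta_qaly = res$direct$delta_qaly
    )
  }
  structure(list(draws = do.call(rbind, rows), n_draws = n_draws,
                 seed = seed),
            class = "psa_draws")
}

#' @export
print.psa_draws <- function(x, ...) {
  cat("PSA:", x$n_draws, "draws (seed", x$seed, ")\n")
  print(summary(x$draws[, -1L]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit (`lambda * delta_qaly - delta_cost > 0`),
#' computed for the reference case (direct costs) and the
#' absenteeism-inclusive case.
#'
#' @param psa A [run_psa()] result.
#' @param lambda_grid Willingness-to-pay grid in dollars per QALY (default
#'   0 to 100,000 by 2,500).
#' @return `data.frame` (lambda, p_ce_direct, p_ce_with_absenteeism).
#' @export
ceac <- function(psa, lambda_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(psa, "psa_draws"), nrow(psa$draws) > 0)
  d <- psa$draws
  out <- t(vapply(lambda_grid, function(lam) {
    c(mean(lam * d$delta_qaly - d$delta_cost_direct > 0),
      mean(lam * d$delta_qaly - d$delta_cost_with_absenteeism > 0))
  }, numeric(2)))
  data.frame(lambda = lambda_grid, p_ce_direct = out[, 1],
             p_ce_with_absenteeism = out[, 2])
}
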