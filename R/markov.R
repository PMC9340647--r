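#' Run the weekly Markov cohort model for one arm
#'
#' Builds the weekly state-occupancy trace over the model horizon. Within the
#' trial follow-up the trace is the linear interpolation of the predicted (or
#' supplied) visit-week distributions; beyond the last visit the cohort
#' evolves by repeated application of the one-week transition matrix
#' (`gap_weeks` equal to the one-week cycle, `peak_dummy = 0`), which is how
#' the regression covariates support extrapolation past the assessment
#' period. Expected hospitalization events per cohort member per week are a
#' toll: `sum_s occupancy[t, s] * weekly_risk(s, arm)`, accrued without
#' altering the occupancy trajectory.
#'
#' The cycle length is one week and no half-cycle correction is applied;
#' week-0 flows are accrued.
#'
#' @param fit A `transition_fit`.
#' @param hfit A `hosp_fit`, or `NULL` for a zero toll.
#' @param arm `"TC"` or `"CM"`.
#' @param baseline Length-4 baseline distribution.
#' @param visit_weeks Trial visit schedule (default 0, 2, 6, 11, 23, 35, 48).
#' @param horizon_weeks Model horizon H; the trace covers weeks `0..H`
#'   (default 260, a five-year horizon). Must be at least the last visit week.
#' @param peak_weeks Passed to [predict_visit_distributions()].
#' @param visit_dists Optional matrix of visit-week distributions overriding
#'   the model predictions (the observed-distribution sensitivity analysis).
#' @return Object of class `cohort_trace`: `arm`, `weeks` (0..H), `occupancy`
#'   ((H+1) x 4, rows sum to 1), `hosp_events_per_week` (length H+1).
#' @export
run_cohort <- function(fit, hfit, arm, baseline,
                       visit_weeks = c(0, 2, 6, 11, 23, 35, 48),
                       horizon_weeks = 260, peak_weeks = 11,
                       visit_dists = NULL) {
  last_visit <- visit_weeks[length(visit_weeks)]
  if (horizon_weeks < last_visit) {
    stop("horizon (", horizon_weeks, ") is before the last visit week (",
         last_visit, ")", call. = FALSE)
  }
  if (is.null(visit_dists)) {
    visit_dists <- predict_visit_distributions(fit, arm, baseline,
                                               visit_weeks, peak_weeks)
  }
  occ <- interpolate_weekly(visit_weeks, visit_dists)
  if (horizon_weeks > last_visit) {
    P1 <- transition_matrix(fit, arm, gap_weeks = 1, peak_dummy = 0)
    extra <- propagate(occ[nrow(occ), ],
                       rep(list(P1), horizon_weeks - last_visit))
    occ <- rbind(occ, extra[-1L, , drop = FALSE])
  }
  rownames(occ) <- 0:horizon_weeks
  hosp <- if (is.null(hfit)) {
    rep(0, horizon_weeks + 1L)
  } else {
    unname(drop(occ %*% hosp_weekly_prob(hfit, arm)))
  }
  structure(list(arm = arm, weeks = 0:horizon_weeks, occupancy = occ,
                 hosp_events_per_week = hosp),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- length(x$weeks) - 1L
  cat("Cohort trace, arm ", x$arm, ", weeks 0..", H, "\n", sep = "")
  cat("time in remission:", round(time_in_remission(x), 3), "\n")
  cat("mean weekly hospitalization events:",
      format(mean(x$hosp_events_per_week), digits = 4), "\n")
  invisible(x)
}

#' Proportion of modeled time spent in remission
#'
#' @param trace A `cohort_trace`.
#' @return Remission occupancy summed over weeks divided by the number of
#'   modeled weeks, in `[0, 1]`.
#' @export
time_in_remission <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  mean(trace$occupancy[, "remission"])
}

#' Export a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(week = trace$weeks, arm = trace$arm,
                   trace$occupancy,
                   hosp_events = trace$hosp_events_per_week,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
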