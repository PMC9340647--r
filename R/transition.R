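#' Health-state transition matrix implied by a fitted model
#'
#' Evaluates the ordered-probit transition probabilities for every lagged
#' state at a given arm, inter-visit gap and peak-dummy setting. Rows are the
#' lagged (origin) states, columns the destination states. Fits with pooled
#' severe/very severe responses place the pooled mass on severe and zero on
#' very severe.
#'
#' @param fit A `transition_fit`.
#' @param arm `"TC"` or `"CM"`.
#' @param gap_weeks Weeks since the last CDAI measurement (covariate value).
#' @param peak_dummy 0 or 1.
#' @return 4 x 4 matrix with rows summing to 1.
#' @export
transition_matrix <- function(fit, arm, gap_weeks, peak_dummy = 0) {
  stopifnot(inherits(fit, "transition_fit"))
  tc <- as.integer(arm == "TC")
  eta <- vapply(seq_len(N_STATES), function(s) {
    sum(covariate_row(s, tc, gap_weeks, peak_dummy) * fit$beta)
  }, numeric(1))
  P <- ordered_probit_probs(eta, fit$tau)
  if (fit$n_cat < N_STATES) {
    P <- cbind(P, matrix(0, nrow(P), N_STATES - fit$n_cat))
  }
  dimnames(P) <- list(state_levels(), state_levels())
  P
}

# left-multiply a distribution through a list of transition matrices
propagate <- function(dist, mats) {
  out <- matrix(NA_real_, length(mats) + 1L, length(dist))
  out[1L, ] <- dist
  for (i in seq_along(mats)) {
    out[i + 1L, ] <- drop(out[i, ] %*% mats[[i]])
  }
  out
}

as_state_distribution <- function(p) {
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-9) {
    stop("invalid state distribution", call. = FALSE)
  }
  pmax(p, 0)
}

#' Predict health-state distributions at the trial visit weeks
#'
#' Starting from a baseline distribution, iterates the fitted transition
#' matrices across consecutive visits: the distribution at visit `j + 1` is
#' the visit-`j` distribution pushed through the transition matrix evaluated
#' at that interval's gap and peak-dummy value.
#'
#' @param fit A `transition_fit`.
#' @param arm `"TC"` or `"CM"`.
#' @param baseline Length-4 probability vector over [state_levels()].
#' @param visit_weeks Increasing visit schedule starting at 0 (default the
#'   trial schedule 0, 2, 6, 11, 23, 35, 48).
#' @param peak_weeks Visit weeks at which `peak_dummy = 1`; must match the
#'   setting used to build the estimation design.
#' @return Matrix `length(visit_weeks)` x 4; row `j` is the distribution at
#'   `visit_weeks[j]`, each row summing to 1.
#' @export
predict_visit_distributions <- function(fit, arm, baseline,
                                        visit_weeks = c(0, 2, 6, 11, 23, 35, 48),
                                        peak_weeks = 11) {
  if (visit_weeks[1L] != 0) stop("visit schedule must start at week 0",
                                 call. = FALSE)
  baseline <- as_state_distribution(baseline)
  gaps <- diff(visit_weeks)
  mats <- lapply(seq_along(gaps), function(j) {
    transition_matrix(fit, arm, gaps[j],
                      as.integer(visit_weeks[j + 1L] %in% peak_weeks))
  })
  occ <- propagate(baseline, mats)
  rownames(occ) <- visit_weeks
  colnames(occ) <- state_levels()
  occ
}

#' Interpolate visit-week distributions to a weekly grid
#'
#' Componentwise linear interpolation of the state-occupancy probabilities
#' between bracketing visits, one row per week from week 0 through the last
#' visit. Linear interpolation of points on the probability simplex preserves
#' the unit sum, so renormalization only kicks in beyond floating-point noise
#' (`|sum - 1| > 1e-12`).
#'
#' @param visit_weeks Increasing integer weeks (at least two).
#' @param visit_dists Matrix `length(visit_weeks)` x 4 of distributions.
#' @return Matrix `(last week + 1)` x 4, rows named by week.
#' @export
interpolate_weekly <- function(visit_weeks, visit_dists) {
  if (length(visit_weeks) < 2L) stop("need at least two visits", call. = FALSE)
  weeks <- seq(visit_weeks[1L], visit_weeks[length(visit_weeks)])
  out <- vapply(seq_len(ncol(visit_dists)), function(s) {
    stats::approx(visit_weeks, visit_dists[, s], xout = weeks)$y
  }, numeric(length(weeks)))
  sums <- rowSums(out)
  fix <- abs(sums - 1) > 1e-12
  if (any(fix)) out[fix, ] <- out[fix, , drop = FALSE] / sums[fix]
  dimnames(out) <- list(weeks, state_levels())
  out
}

#' Observed visit-week state distributions
#'
#' Empirical state frequencies at each visit week, for the sensitivity
#' analysis that feeds observed rather than model-predicted distributions
#' into the cohort evaluation.
#'
#' @param trial Imputed trial table.
#' @param arm `"TC"` or `"CM"`.
#' @param visit_weeks Visit schedule to tabulate.
#' @return Matrix `length(visit_weeks)` x 4 of observed frequencies.
#' @export
empirical_visit_distributions <- function(trial, arm,
                                          visit_weeks = c(0, 2, 6, 11, 23, 35, 48)) {
  trial <- trial[trial$arm == arm, , drop = FALSE]
  if (nrow(trial) == 0L) stop("no observations for arm ", arm, call. = FALSE)
  st <- state_code(state_from_cdai(trial$cdai))
  out <- t(vapply(visit_weeks, function(w) {
    s <- st[trial$week == w]
    if (length(s) == 0L) stop("no observations at week ", w, call. = FALSE)
    tabulate(s, N_STATES) / length(s)
  }, numeric(N_STATES)))
  dimnames(out) <- list(visit_weeks, state_levels())
  out
}

#' Weekly hospitalization probability by state
#'
#' Converts the fitted per-interval hospitalization risk to a weekly
#' probability per health state and arm: the probit is evaluated at the
#' reference interval length `gap_ref` carried by the fit, and the interval
#' risk `p` becomes `1 - (1 - p)^(1/gap_ref)`.
#'
#' @param hfit A `hosp_fit`.
#' @param arm `"TC"` or `"CM"`.
#' @return Named length-4 vector of weekly probabilities.
#' @export
hosp_weekly_prob <- function(hfit, arm) {
  stopifnot(inherits(hfit, "hosp_fit"))
  tc <- as.integer(arm == "TC")
  p_int <- vapply(seq_len(N_STATES), function(s) {
    x <- c(1, covariate_row(s, tc, hfit$gap_ref, 0))
    stats::pnorm(sum(x * hfit$gamma))
  }, numeric(1))
  stats::setNames(1 - (1 - p_int)^(1 / hfit$gap_ref), state_levels())
}
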