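#' Configuration of the synthetic trial generator
#'
#' Defines the ground-truth data-generating process for a two-arm
#' tight-control versus conventional-management trial with the standard
#' visit schedule. Defaults emulate the published study conditions: 122
#' patients per arm, visits at weeks 0, 2, 6, 11, 23, 35 and 48, a baseline
#' health-state mix of 74% moderate and 26% severe/very severe (split 20/6
#' between the two pooled strata, an assumption since only the pooled figure
#' is reported), ordinal state dynamics from an ordered-probit process with a
#' treatment effect favouring tight control, and state-dependent
#' hospitalization intensities calibrated so the expected crude rates are
#' 28.0 (CM) and 13.2 (TC) events per 100 patient-years.
#'
#' @param n_per_arm Patients per arm (default 122).
#' @param visit_weeks Visit schedule.
#' @param baseline_state_probs Length-4 baseline state distribution.
#' @param true_beta,true_tau Ground-truth ordered-probit parameters on the
#'   covariate block of [build_design()].
#' @param hosp_rate_cm,hosp_rate_tc Target crude hospitalization rates, in
#'   events per 100 patient-years.
#' @param hosp_state_multipliers Relative hospitalization intensity by the
#'   interval's lagged state (worse states carry higher risk).
#' @param absenteeism_mean_by_state,absenteeism_sd Mean work-hours-missed
#'   fraction per state and Gaussian noise SD; observations are clipped to
#'   `[0, 1]`.
#' @param absenteeism_weeks Weeks at which the work-productivity instrument
#'   is administered (default 0, 11, 23, 35, 48).
#' @param missing_rate Probability that a non-baseline CDAI value is missing
#'   completely at random.
#' @param peak_weeks Visit weeks at which the generating process applies the
#'   peak-remission dummy.
#' @return Object of class `generator_config` (a list).
#' @export
generator_config <- function(n_per_arm = 122,
                             visit_weeks = c(0, 2, 6, 11, 23, 35, 48),
                             baseline_state_probs = c(0, 0.74, 0.20, 0.06),
                             true_beta = default_true_beta(),
                             true_tau = c(0.6, 2.0, 3.0),
                             hosp_rate_cm = 28.0,
                             hosp_rate_tc = 13.2,
                             hosp_state_multipliers = c(0.5, 1, 2, 3),
                             absenteeism_mean_by_state = c(0.02, 0.15, 0.35, 0.55),
                             absenteeism_sd = 0.05,
                             absenteeism_weeks = c(0, 11, 23, 35, 48),
                             missing_rate = 0.05,
                             peak_weeks = 11) {
  stopifnot(n_per_arm >= 1, length(baseline_state_probs) == N_STATES,
            abs(sum(baseline_state_probs) - 1) < 1e-9,
            all(baseline_state_probs >= 0),
            hosp_rate_cm >= 0, hosp_rate_tc >= 0,
            all(hosp_state_multipliers >= 0),
            missing_rate >= 0, missing_rate < 1)
  check_tau(true_tau)
  structure(as.list(environment()), class = "generator_config")
}

#' Default ground-truth transition coefficients for the generator
#'
#' Lagged-state effects give strong state persistence, the negative
#' treatment terms make tight control more likely to hold or improve the
#' state (more so from worse states), the small gap effect lets longer
#' intervals drift slightly toward improvement, and the peak dummy boosts
#' remission around the peak-remission visit.
#'
#' @return Named coefficient vector on the [build_design()] covariate block.
#' @export
default_true_beta <- function() {
  c(lag_moderate = 1.3, lag_severe = 2.3, lag_very_severe = 3.0,
    tc = -0.15, tc_lag_moderate = -0.08, tc_lag_severe = -0.15,
    tc_lag_very_severe = -0.2, gap_weeks = -0.005, peak_dummy = -0.25)
}

# ground-truth transition matrix (reuses the fitted-model plumbing via a
# zero-covariance transition_fit)
true_fit <- function(config) {
  transition_fit(beta = config$true_beta, tau = config$true_tau)
}

# per-week base hospitalization intensity for one arm, calibrated so the
# expected crude rate over the visit schedule equals the target:
# expected events per patient = lambda0 * sum_j gap_j * E[m(state at j-1)]
# must equal (rate/100) * (follow-up years)
hosp_base_intensity <- function(config, arm) {
  rate <- if (arm == "TC") config$hosp_rate_tc else config$hosp_rate_cm
  vw <- config$visit_weeks
  occ <- predict_visit_distributions(true_fit(config), arm,
                                     config$baseline_state_probs, vw,
                                     config$peak_weeks)
  gaps <- diff(vw)
  em <- drop(occ[-nrow(occ), , drop = FALSE] %*% config$hosp_state_multipliers)
  denom <- sum(gaps * em)
  follow_years <- (vw[length(vw)] - vw[1]) / 52
  (rate / 100) * follow_years / denom
}

#' Generate a synthetic longitudinal trial
#'
#' Simulates patient-level observations from the ground truth in `config`:
#' baseline states are drawn from the baseline mix and assigned a CDAI score
#' uniformly within the state's band; each later visit's state is drawn from
#' the ordered-probit transition process at the true parameters and its CDAI
#' re-drawn within the realized state's band (so the CDAI-to-state mapping
#' inverts the draw exactly); inter-visit hospitalization counts are Poisson
#' with a state- and arm-dependent intensity calibrated to the configured
#' crude rates; absenteeism is observed at the instrument weeks as the state
#' mean plus Gaussian noise clipped to `[0, 1]`; CDAI missingness is applied
#' completely at random at the configured rate, never at baseline.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the output is bit-reproducible given the same
#'   config and seed.
#' @return Long-format `data.frame` with the trial-table schema of
#'   [read_trial_csv()] plus a `true_state` column carrying the generating
#'   state (useful for validation; drop it to mimic observed data).
#' @export
generate_trial <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  vw <- config$visit_weeks
  n_visits <- length(vw)
  gaps <- diff(vw)
  arms <- rep(c("CM", "TC"), each = config$n_per_arm)
  n <- length(arms)
  ids <- sprintf("P%04d", seq_len(n))
  lam0 <- c(CM = hosp_base_intensity(config, "CM"),
            TC = hosp_base_intensity(config, "TC"))
  bounds <- state_cdai_bounds()
  tf <- true_fit(config)
  # per-arm transition matrices for each interval
  mats <- lapply(c(CM = "CM", TC = "TC"), function(a) {
    lapply(seq_along(gaps), function(j) {
      transition_matrix(tf, a, gaps[j],
                        as.integer(vw[j + 1L] %in% config$peak_weeks))
    })
  })
  state <- matrix(NA_integer_, n, n_visits)
  state[, 1L] <- sample.int(N_STATES, n, replace = TRUE,
                            prob = config$baseline_state_probs)
  hosp <- matrix(0L, n, n_visits)
  for (j in seq_along(gaps)) {
    u <- stats::runif(n)
    for (a in c("CM", "TC")) {
      in_arm <- arms == a
      P <- mats[[a]][[j]]
      cum <- t(apply(P, 1, cumsum))
      lag <- state[in_arm, j]
      # inverse-CDF draw of the next state given each patient's lagged state
      state[in_arm, j + 1L] <- 1L +
        rowSums(u[in_arm] > cum[lag, , drop = FALSE] + 1e-15)
      lambda <- lam0[[a]] * config$hosp_state_multipliers[lag] * gaps[j]
      hosp[in_arm, j + 1L] <- stats::rpois(sum(in_arm), lambda)
    }
  }
  cdai <- matrix(stats::runif(n * n_visits), n, n_visits)
  cdai <- bounds[state, "lower"] +
    cdai * (bounds[state, "upper"] - bounds[state, "lower"])
  dim(cdai) <- dim(state)
  # MCAR missingness, never at baseline
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_visits) < config$missing_rate,
                   n, n_visits)
    miss[, 1L] <- FALSE
    cdai[miss] <- NA_real_
  }
  absent <- matrix(NA_real_, n, n_visits)
  obs_cols <- which(vw %in% config$absenteeism_weeks)
  for (j in obs_cols) {
    raw <- config$absenteeism_mean_by_state[state[, j]] +
      stats::rnorm(n, 0, config$absenteeism_sd)
    absent[, j] <- pmin(pmax(raw, 0), 1)
  }
  out <- data.frame(
    patient_id = rep(ids, each = n_visits),
    arm = rep(arms, each = n_visits),
    week = rep(vw, times = n),
    cdai = as.vector(t(cdai)),
    hosp_events = as.vector(t(hosp)),
    absenteeism_frac = as.vector(t(absent)),
    true_state = factor(state_levels()[as.vector(t(state))],
                        levels = state_levels(), ordered = TRUE),
    stringsAsFactors = FALSE
  )
  out
}

#' Crude hospitalization rate per 100 patient-years
#'
#' Events divided by follow-up time, where each patient contributes the span
#' from their first to their last recorded visit.
#'
#' @param trial Trial table.
#' @param arm `"TC"` or `"CM"`.
#' @return Events per 100 patient-years.
#' @export
#' @examples
#' # 2 events over 10 person-years -> 20 per 100 patient-years
crude_hosp_rate <- function(trial, arm) {
  td <- trial[trial$arm == arm, , drop = FALSE]
  if (nrow(td) == 0L) stop("no observations for arm ", arm, call. = FALSE)
  span <- tapply(td$week, td$patient_id, function(w) max(w) - min(w))
  py <- sum(span) / 52
  if (py <= 0) stop("zero follow-up time", call. = FALSE)
  100 * sum(td$hosp_events, na.rm = TRUE) / py
}

#' Write a generator configuration to YAML
#'
#' @param config A `generator_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_yaml <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.factor(x)) as.character(x) else x
  }), path)
  invisible(path)
}
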