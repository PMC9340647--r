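# Shared fixtures, all generated in code.

# tiny hand-written trial table: two patients, complete schedule
small_trial <- function() {
  sched <- c(0, 2, 6, 11, 23, 35, 48)
  data.frame(
    patient_id = rep(c("a", "b"), each = 7),
    arm = rep(c("CM", "TC"), each = 7),
    week = rep(sched, 2),
    cdai = c(200, 180, 120, 140, 100, 90, 80,
             320, 310, 250, 200, 160, 140, 100),
    hosp_events = c(0, 1, 0, 0, 0, 0, 0,
                    0, 0, 1, 0, 0, 0, 0),
    absenteeism_frac = NA_real_,
    stringsAsFactors = FALSE
  )
}

# fit whose transition matrix is the identity (mass never moves)
identity_fit <- function() {
  transition_fit(
    beta = c(lag_moderate = 200, lag_severe = 400, lag_very_severe = 600,
             tc = 0, tc_lag_moderate = 0, tc_lag_severe = 0,
             tc_lag_very_severe = 0, gap_weeks = 0, peak_dummy = 0),
    tau = c(100, 300, 500)
  )
}

# arbitrary smooth fit used by the propagation oracles
toy_fit <- function() {
  transition_fit(
    beta = c(lag_moderate = 0.9, lag_severe = 1.7, lag_very_severe = 2.4,
             tc = -0.3, tc_lag_moderate = -0.1, tc_lag_severe = -0.2,
             tc_lag_very_severe = -0.2, gap_weeks = 0.01, peak_dummy = -0.2),
    tau = c(0.5, 1.6, 2.6)
  )
}

# effectively two-state fit: thresholds 2 and 3 are unreachable
two_state_fit <- function(beta_mod = 0.8, tau1 = 0.4) {
  transition_fit(
    beta = c(lag_moderate = beta_mod, lag_severe = 0, lag_very_severe = 0,
             tc = 0, tc_lag_moderate = 0, tc_lag_severe = 0,
             tc_lag_very_severe = 0, gap_weeks = 0, peak_dummy = 0),
    tau = c(tau1, 30, 60)
  )
}

# hospitalization fit with a flat weekly risk p under any covariates
flat_hosp_fit <- function(p_weekly, gap_ref = 1) {
  hosp_fit(
    gamma = c(intercept = stats::qnorm(p_weekly), lag_moderate = 0,
              lag_severe = 0, lag_very_severe = 0, tc = 0,
              tc_lag_moderate = 0, tc_lag_severe = 0,
              tc_lag_very_severe = 0, gap_weeks = 0, peak_dummy = 0),
    gap_ref = gap_ref
  )
}

# simulate design rows + ordinal responses from known parameters
simulate_design <- function(n, beta, tau, seed, tc_share = 0.5) {
  set.seed(seed)
  design <- data.frame(
    lag_state = sample(state_levels(), n, replace = TRUE,
                       prob = c(0.35, 0.4, 0.18, 0.07)),
    treatment = stats::rbinom(n, 1, tc_share),
    gap_weeks = sample(c(2, 4, 5, 12), n, replace = TRUE),
    peak_dummy = stats::rbinom(n, 1, 0.15)
  )
  X <- crohncea:::design_matrix(design)
  eta <- drop(X %*% beta)
  u <- stats::runif(n)
  cum <- vapply(tau, function(t) stats::pnorm(t - eta), numeric(n))
  y <- 1L + rowSums(u > cum)
  design$response_state <- factor(state_levels()[y],
                                  levels = state_levels(), ordered = TRUE)
  design$hosp_events <- 0L
  design
}
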