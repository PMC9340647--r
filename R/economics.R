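#' Economic parameters for the cost-utility analysis
#'
#' Bundles every cost, utility, wage and discount input with its base value
#' and, where available, the low/high range used by the one-way sensitivity
#' analysis. Monetary values are 2020 Canadian dollars.
#'
#' Unit costs and wage inputs default to published Canadian payer values:
#' hospitalization $16,491 per admission (range 14,687-22,066), fecal
#' calprotectin test $40.00, C-reactive protein test $10.15 (3.72-16.60),
#' adalimumab $785.45 per 40 mg dose, biosimilar discount 0 (0-0.40), hourly
#' wage $29.51 (24.10-32.73), 36.9 hours per standard work week (34.8-37.2),
#' annual discount rate 1.5% (0-3%), willingness to pay $50,000 per QALY.
#'
#' The per-state utility tables and the other-direct-medical weekly costs are
#' *synthetic placeholders*: the published EQ-5D-from-CDAI mapping and the
#' severity-stratified resource-use source behind them are not reproduced
#' here, so these defaults merely preserve the severity ordering (worse state,
#' lower utility, higher cost) and should be replaced with study-specific
#' values for real analyses.
#'
#' @param ... Named overrides of any default listed below.
#' @return Object of class `econ_params` (a list).
#' @export
#' @examples
#' p <- econ_params(biosimilar_discount = 0.4)
#' p$hosp_cost_per_admission
econ_params <- function(...) {
  p <- list(
    hosp_cost_per_admission = 16491,
    fcp_test = 40.00,
    crp_test = 10.15,
    adalimumab_per_40mg = 785.45,
    biosimilar_discount = 0,
    hourly_wage = 29.51,
    hours_per_week = 36.9,
    annual_discount = 0.015,
    wtp = 50000,
    # synthetic placeholder: weekly other direct medical cost by state ($)
    other_direct_weekly_by_state = c(remission = 25, moderate = 70,
                                     severe = 160, very_severe = 260),
    # synthetic placeholder utilities; eq5d is the reference set, sf6d the
    # narrower-range alternative used in sensitivity analysis
    utility_eq5d_by_state = c(remission = 0.88, moderate = 0.73,
                              severe = 0.58, very_severe = 0.45),
    utility_sf6d_by_state = c(remission = 0.80, moderate = 0.71,
                              severe = 0.63, very_severe = 0.56),
    utility_source = "eq5d",
    # absenteeism attaches to health states (documented modelling assumption;
    # trial reporting is arm-level)
    absenteeism_frac_by_state = c(remission = 0.02, moderate = 0.15,
                                  severe = 0.35, very_severe = 0.55),
    hosp_utility_decrement = 0,
    dose_schedule = NULL,
    ranges = list(
      hosp_cost_per_admission = c(14687, 22066),
      crp_test = c(3.72, 16.60),
      biosimilar_discount = c(0, 0.40),
      annual_discount = c(0, 0.03),
      hourly_wage = c(24.10, 32.73),
      hours_per_week = c(34.8, 37.2),
      baseline_moderate_pct = c(0, 100),
      utility_source = "sf6d"   # one-sided alternative
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  if (is.null(p$dose_schedule)) p$dose_schedule <- default_dose_schedule()
  validate_econ_params(p)
}

validate_econ_params <- function(p) {
  money <- c("hosp_cost_per_admission", "fcp_test", "crp_test",
             "adalimumab_per_40mg", "hourly_wage", "hours_per_week", "wtp")
  for (nm in money) {
    if (p[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  for (nm in c("biosimilar_discount", "annual_discount")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]",
                                         call. = FALSE)
  }
  for (nm in c("utility_eq5d_by_state", "utility_sf6d_by_state")) {
    if (any(p[[nm]] < 0 | p[[nm]] > 1)) stop(nm, " must be in [0, 1]",
                                             call. = FALSE)
  }
  if (any(p$absenteeism_frac_by_state < 0 | p$absenteeism_frac_by_state > 1)) {
    stop("absenteeism fractions must be in [0, 1]", call. = FALSE)
  }
  if (!p$utility_source %in% c("eq5d", "sf6d")) {
    stop("utility_source must be 'eq5d' or 'sf6d'", call. = FALSE)
  }
  structure(p, class = "econ_params")
}

active_utilities <- function(params) {
  if (params$utility_source == "sf6d") params$utility_sf6d_by_state
  else params$utility_eq5d_by_state
}

#' Weekly discount factor
#'
#' @param week Week index (0 = model start).
#' @param annual_rate Annual discount rate (e.g. 0.015 for 1.5%).
#' @return `(1 + annual_rate)^(-week / 52)`.
#' @export
#' @examples
#' discount_factor(52, 0.015)  # one year: 1/1.015
discount_factor <- function(week, annual_rate) {
  if (annual_rate < 0) stop("discount rate must be non-negative",
                            call. = FALSE)
  (1 + annual_rate)^(-week / 52)
}

#' Biomarker monitoring schedule
#'
#' Tight-control patients receive fecal calprotectin and C-reactive protein
#' tests at weeks 0 and 11 and every 12 weeks thereafter; conventional
#' management has no scheduled biomarker monitoring.
#'
#' @param horizon_weeks Model horizon.
#' @param arm `"TC"` or `"CM"`.
#' @return Integer vector of test weeks (empty for CM).
#' @export
#' @examples
#' biomarker_schedule(48, "TC")  # 0 11 23 35 47
biomarker_schedule <- function(horizon_weeks, arm = "TC") {
  if (horizon_weeks < 0) stop("horizon must be non-negative", call. = FALSE)
  if (arm != "TC") return(integer(0))
  weeks <- c(0, if (horizon_weeks >= 11) seq(11, horizon_weeks, by = 12))
  as.integer(weeks)
}

#' Default adalimumab dose schedule
#'
#' Expected 40-mg dose units per cohort member per week. Both arms follow
#' induction (160 mg at week 0, 80 mg at week 2) then 40 mg every other week
#' from week 4. A fraction of each cohort escalates to 40 mg weekly, so
#' off-weeks carry the escalated fraction as expected units. Under tight
#' control, escalation is biomarker-driven: earlier (from the first
#' post-induction biomarker review) and more frequent. Under conventional
#' management, escalation is symptom-driven: later and less frequent. The
#' escalated fractions and timing are modelling inputs, not trial-reported
#' quantities.
#'
#' @param esc_frac_tc Fraction of TC patients dose-escalated (default 0.4).
#' @param esc_week_tc Week from which TC escalation applies (default 11, the
#'   first biomarker-driven adjustment opportunity after induction).
#' @param esc_frac_cm Fraction of CM patients eventually dose-escalated on
#'   symptoms (default 0.15).
#' @param esc_week_cm Week from which CM escalation applies (default 26).
#' @return Function `(arm, week) -> expected 40-mg units`, vectorized over
#'   `week`.
#' @export
default_dose_schedule <- function(esc_frac_tc = 0.4, esc_week_tc = 11,
                                  esc_frac_cm = 0.15, esc_week_cm = 26) {
  force(esc_frac_tc); force(esc_week_tc)
  force(esc_frac_cm); force(esc_week_cm)
  function(arm, week) {
    units <- ifelse(week == 0, 4,
             ifelse(week == 2, 2,
             ifelse(week >= 4 & week %% 2 == 0, 1, 0)))
    esc_frac <- if (arm == "TC") esc_frac_tc else esc_frac_cm
    esc_week <- if (arm == "TC") esc_week_tc else esc_week_cm
    units + ifelse(week >= esc_week & week %% 2 == 1, esc_frac, 0)
  }
}

#' Adalimumab cost in one model week
#'
#' @param arm `"TC"` or `"CM"`.
#' @param week Model week (vectorized).
#' @param dose_schedule Function `(arm, week) -> 40-mg units`; see
#'   [default_dose_schedule()].
#' @param params An `econ_params`.
#' @return Undiscounted cost: `units * adalimumab_per_40mg *
#'   (1 - biosimilar_discount)`.
#' @export
adalimumab_cost_week <- function(arm, week, dose_schedule, params) {
  units <- dose_schedule(arm, week)
  if (any(units < 0)) stop("negative dose units", call. = FALSE)
  units * params$adalimumab_per_40mg * (1 - params$biosimilar_discount)
}

#' Absenteeism cost in one model week
#'
#' Expected hours missed out of a standard work week, monetized at the
#' average hourly wage (human-capital approach).
#'
#' @param occupancy Length-4 state distribution.
#' @param params An `econ_params`.
#' @return `sum_s occupancy[s] * absenteeism_frac[s] * hours_per_week *
#'   hourly_wage`.
#' @export
absenteeism_cost_week <- function(occupancy, params) {
  sum(occupancy * params$absenteeism_frac_by_state) *
    params$hours_per_week * params$hourly_wage
}

#' Quality-adjusted life-years accrued in one model week
#'
#' @param occupancy Length-4 state distribution.
#' @param params An `econ_params`.
#' @return `sum_s occupancy[s] * utility(s) / 52`.
#' @export
qaly_week <- function(occupancy, params) {
  sum(occupancy * active_utilities(params)) / 52
}

# discounted per-arm component totals for one trace
arm_components <- function(trace, params) {
  H <- length(trace$weeks) - 1L
  df <- discount_factor(trace$weeks, params$annual_discount)
  occ <- trace$occupancy
  util <- active_utilities(params)
  hosp <- sum(df * trace$hosp_events_per_week) * params$hosp_cost_per_admission
  ada <- sum(df * adalimumab_cost_week(trace$arm, trace$weeks,
                                       params$dose_schedule, params))
  bio_weeks <- biomarker_schedule(H, trace$arm)
  biomarker <- sum(discount_factor(bio_weeks, params$annual_discount)) *
    (params$fcp_test + params$crp_test)
  other <- sum(df * drop(occ %*% params$other_direct_weekly_by_state))
  absent <- sum(df * drop(occ %*% params$absenteeism_frac_by_state)) *
    params$hours_per_week * params$hourly_wage
  qalys <- sum(df * drop(occ %*% util)) / 52 -
    params$hosp_utility_decrement * sum(df * trace$hosp_events_per_week)
  c(hospitalization = hosp, adalimumab = ada, biomarker = biomarker,
    other_direct = other, total_direct = hosp + ada + biomarker + other,
    absenteeism = absent,
    total_with_absenteeism = hosp + ada + biomarker + other + absent,
    qalys = qalys)
}

#' Incremental cost-effectiveness summary
#'
#' Classifies an (incremental cost, incremental effect) pair: `"DOMINANT"`
#' when the new strategy saves money and gains QALYs, `"DOMINATED"` when it
#' costs more and loses QALYs, otherwise an ICER; the net monetary benefit at
#' the willingness-to-pay threshold is always reported.
#'
#' @param delta_cost Incremental cost (new minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness to pay per QALY (default 50,000).
#' @return List: `delta_cost`, `delta_qaly`, `icer` (NA when undefined or
#'   under dominance), `label` (`"ICER"`, `"DOMINANT"`, `"DOMINATED"`, or
#'   `"UNDEFINED"` when `delta_qaly == 0`), `nmb`.
#' @export
#' @examples
#' icer_summary(8886, 0.246)
icer_summary <- function(delta_cost, delta_qaly, wtp = 50000) {
  label <- if (delta_qaly > 0 && delta_cost < 0) "DOMINANT"
    else if (delta_qaly < 0 && delta_cost > 0) "DOMINATED"
    else if (delta_qaly == 0) "UNDEFINED"
    else "ICER"
  icer <- if (label == "ICER") delta_cost / delta_qaly else NA_real_
  list(delta_cost = delta_cost, delta_qaly = delta_qaly, icer = icer,
       label = label, nmb = wtp * delta_qaly - delta_cost)
}

#' Evaluate the cost-utility comparison of two cohort traces
#'
#' Maps the tight-control and conventional-management traces to discounted
#' cost components and QALYs and computes incremental results both for the
#' reference case (direct medical costs only) and for the non-reference case
#' that adds absenteeism.
#'
#' @param trace_tc,trace_cm `cohort_trace` objects sharing a horizon.
#' @param params An `econ_params`.
#' @return Object of class `cea_result`: `components` (2 x 8 matrix of per-arm
#'   discounted totals), `direct` and `with_absenteeism` incremental
#'   summaries (see [icer_summary()]), `wtp`, `horizon_weeks`.
#' @export
evaluate_cea <- function(trace_tc, trace_cm, params = econ_params()) {
  stopifnot(inherits(trace_tc, "cohort_trace"),
            inherits(trace_cm, "cohort_trace"))
  if (length(trace_tc$weeks) != length(trace_cm$weeks)) {
    stop("traces must share the same horizon", call. = FALSE)
  }
  comp <- rbind(TC = arm_components(trace_tc, params),
                CM = arm_components(trace_cm, params))
  d_qaly <- comp["TC", "qalys"] - comp["CM", "qalys"]
  structure(list(
    components = comp,
    direct = icer_summary(comp["TC", "total_direct"] -
                            comp["CM", "total_direct"], d_qaly, params$wtp),
    with_absenteeism = icer_summary(
      comp["TC", "total_with_absenteeism"] -
        comp["CM", "total_with_absenteeism"], d_qaly, params$wtp),
    wtp = params$wtp,
    horizon_weeks = length(trace_tc$weeks) - 1L
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat("Cost-effectiveness evaluation over ", x$horizon_weeks,
      "-week time horizon\n\n", sep = "")
  cat("Total direct costs, $\n")
  cat("  TC         ", fmt(x$components["TC", "total_direct"]), "\n")
  cat("  CM         ", fmt(x$components["CM", "total_direct"]), "\n")
  cat("  Difference ", fmt(x$direct$delta_cost), "\n")
  cat("Total costs including absenteeism, $\n")
  cat("  TC         ", fmt(x$components["TC", "total_with_absenteeism"]), "\n")
  cat("  CM         ", fmt(x$components["CM", "total_with_absenteeism"]), "\n")
  cat("  Difference ", fmt(x$with_absenteeism$delta_cost), "\n")
  cat("Total QALYs\n")
  cat("  TC         ", round(x$components["TC", "qalys"], 3), "\n")
  cat("  CM         ", round(x$components["CM", "qalys"], 3), "\n")
  cat("  Difference ", round(x$direct$delta_qaly, 3), "\n")
  cat("ICER ($ per QALY)\n")
  cat("  Direct costs only     ",
      if (x$direct$label == "ICER") fmt(x$direct$icer) else x$direct$label,
      "\n")
  cat("  Including absenteeism ",
      if (x$with_absenteeism$label == "ICER") fmt(x$with_absenteeism$icer)
      else x$with_absenteeism$label, "\n")
  invisible(x)
}

#' Serialize a CEA result to JSON
#'
#' @param result A `cea_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cea_json <- function(result, path) {
  out <- unclass(result)
  out$components <- as.data.frame(out$components)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
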