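test_that("weekly discount factors follow the annual rate", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(37, 0), 1)
  expect_equal(discount_factor(52, 0.015), 1 / 1.015, tolerance = 1e-12)
  expect_equal(discount_factor(104, 0.015), 1.015^-2, tolerance = 1e-12)
  expect_error(discount_factor(10, -0.01), "non-negative")
})

test_that("biomarker schedule is weeks 0, 11, then every 12, TC only", {
  expect_equal(biomarker_schedule(48, "TC"), c(0L, 11L, 23L, 35L, 47L))
  expect_equal(biomarker_schedule(10, "TC"), 0L)
  expect_length(biomarker_schedule(260, "CM"), 0)
  p <- econ_params()
  undiscounted <- length(biomarker_schedule(48, "TC")) *
    (p$fcp_test + p$crp_test)
  expect_equal(undiscounted, 250.75)
})

test_that("adalimumab costs are dose units times unit price", {
  p <- econ_params()
  # pure q2w maintenance year: 26 doses
  sched <- default_dose_schedule(esc_frac_tc = 0, esc_frac_cm = 0)
  maint_weeks <- 4:55
  expect_equal(sum(sched("CM", maint_weeks)), 26)
  expect_equal(sum(adalimumab_cost_week("CM", maint_weeks, sched, p)),
               26 * 785.45, tolerance = 1e-9)
  expect_equal(sum(adalimumab_cost_week("CM", maint_weeks, sched, p)),
               20421.70, tolerance = 1e-9)
  # biosimilar discount scales linearly
  p40 <- econ_params(biosimilar_discount = 0.40)
  expect_equal(adalimumab_cost_week("TC", 12, sched, p40),
               0.6 * adalimumab_cost_week("TC", 12, sched, p))
  # no dose, no cost
  expect_equal(adalimumab_cost_week("CM", 5, sched, p), 0)
  expect_error(adalimumab_cost_week("CM", 5, function(arm, week) -1, p),
               "negative")
})

test_that("absenteeism cost monetizes expected hours missed", {
  p <- econ_params()
  flat10 <- econ_params(absenteeism_frac_by_state = rep(0.10, 4))
  expect_equal(absenteeism_cost_week(c(0.25, 0.25, 0.25, 0.25), flat10),
               0.10 * 36.9 * 29.51, tolerance = 1e-12)
  expect_equal(absenteeism_cost_week(c(0.25, 0.25, 0.25, 0.25), flat10),
               108.89, tolerance = 1e-2)
  zero <- econ_params(absenteeism_frac_by_state = rep(0, 4))
  expect_equal(absenteeism_cost_week(c(0, 0.5, 0.5, 0), zero), 0)
  # all mass in one state picks that state's fraction
  expect_equal(absenteeism_cost_week(c(0, 0, 1, 0), p),
               p$absenteeism_frac_by_state[["severe"]] * 36.9 * 29.51)
})

test_that("weekly QALYs are the utility mixture over 52", {
  perfect <- econ_params(utility_eq5d_by_state = rep(1, 4))
  expect_equal(qaly_week(c(0.25, 0.25, 0.25, 0.25), perfect), 1 / 52)
  mix <- econ_params(utility_eq5d_by_state = c(0.8, 0.6, 0.4, 0.2))
  expect_equal(qaly_week(c(0.5, 0.5, 0, 0), mix), 0.7 / 52)
  # five years in perfect health, undiscounted, bounds the accrual at ~5 QALYs
  trace <- run_cohort(identity_fit(), NULL, "CM", c(1, 0, 0, 0),
                      horizon_weeks = 260)
  res <- evaluate_cea(trace, trace,
                      econ_params(utility_eq5d_by_state = rep(1, 4),
                                  annual_discount = 0))
  expect_equal(unname(res$components["TC", "qalys"]), 261 / 52)
  expect_lt(abs(res$components["TC", "qalys"] - 5), 1 / 52)
})

test_that("incremental summaries classify dominance and compute the ICER", {
  ref <- icer_summary(8886, 0.246)
  expect_equal(ref$icer, 8886 / 0.246)
  expect_equal(ref$label, "ICER")
  expect_equal(ref$nmb, 50000 * 0.246 - 8886)
  dom <- icer_summary(-9597, 0.246)
  expect_equal(dom$label, "DOMINANT")
  expect_true(is.na(dom$icer))
  expect_equal(icer_summary(100, -0.1)$label, "DOMINATED")
  zero <- icer_summary(0, 0)
  expect_equal(zero$label, "UNDEFINED")
  expect_equal(zero$nmb, 0)
})

test_that("identical traces produce a null comparison", {
  trace <- run_cohort(toy_fit(), flat_hosp_fit(0.01), "CM",
                      c(0, 0.74, 0.2, 0.06), horizon_weeks = 104)
  res <- evaluate_cea(trace, trace)
  expect_equal(res$direct$delta_cost, 0)
  expect_equal(res$direct$delta_qaly, 0)
  expect_equal(res$direct$nmb, 0)
})

make_eval <- function(params) {
  fit <- toy_fit()
  hf <- flat_hosp_fit(0.005)
  baseline <- c(0, 0.74, 0.2, 0.06)
  tc <- run_cohort(fit, hf, "TC", baseline, horizon_weeks = 260)
  cm <- run_cohort(fit, hf, "CM", baseline, horizon_weeks = 260)
  evaluate_cea(tc, cm, params)
}

test_that("direct components add up exactly to the direct total", {
  res <- make_eval(econ_params())
  comp <- res$components
  for (arm in c("TC", "CM")) {
    expect_equal(comp[arm, "total_direct"],
                 sum(comp[arm, c("hospitalization", "adalimumab",
                                 "biomarker", "other_direct")]))
    expect_equal(comp[arm, "total_with_absenteeism"],
                 comp[arm, "total_direct"] + comp[arm, "absenteeism"])
  }
})

test_that("discounted totals are monotone non-increasing in the rate", {
  rates <- c(0, 0.015, 0.03)
  totals <- vapply(rates, function(r) {
    res <- make_eval(econ_params(annual_discount = r))
    c(res$components["TC", "total_direct"],
      res$components["TC", "qalys"],
      res$components["CM", "total_with_absenteeism"])
  }, numeric(3))
  for (row in 1:3) expect_true(all(diff(totals[row, ]) < 0))
})

test_that("the ICER is invariant to a cost stream common to both arms", {
  res0 <- make_eval(econ_params())
  p_shift <- econ_params(other_direct_weekly_by_state =
                           econ_params()$other_direct_weekly_by_state + 100)
  res1 <- make_eval(p_shift)
  expect_equal(res1$direct$icer, res0$direct$icer, tolerance = 1e-9)
  expect_gt(res1$components["TC", "total_direct"],
            res0$components["TC", "total_direct"])
})

test_that("the SF-6D utility set narrows the QALY gain", {
  res_eq <- make_eval(econ_params())
  res_sf <- make_eval(econ_params(utility_source = "sf6d"))
  expect_lt(res_sf$direct$delta_qaly, res_eq$direct$delta_qaly)
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(econ_params(annual_discount = 1.5), "\\[0, 1\\]")
  expect_error(econ_params(hourly_wage = -1), "non-negative")
  expect_error(econ_params(nonsense = 1), "unknown")
  expect_error(econ_params(utility_source = "vas"), "eq5d")
})
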