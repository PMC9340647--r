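make_ctx <- function(horizon = 156, params = econ_params()) {
  cea_context(toy_fit(), flat_hosp_fit(0.005), c(0, 0.74, 0.2, 0.06),
              params, horizon_weeks = horizon)
}

test_that("a degenerate range reproduces the base ICER exactly", {
  params <- econ_params()
  params$ranges <- list(hosp_cost_per_admission = c(16491, 16491))
  ctx <- make_ctx(params = params)
  tor <- run_owsa(ctx)
  expect_equal(tor$icer_low, attr(tor, "base_icer"))
  expect_equal(tor$icer_high, attr(tor, "base_icer"))
  expect_equal(tor$extent, 0)
})

test_that("discount-rate variation brackets the base ICER with small spread", {
  params <- econ_params()
  params$ranges <- list(annual_discount = c(0, 0.03))
  ctx <- make_ctx(params = params)
  tor <- run_owsa(ctx)
  base <- attr(tor, "base_icer")
  lo <- min(tor$icer_low, tor$icer_high)
  hi <- max(tor$icer_low, tor$icer_high)
  expect_lte(lo, base)
  expect_gte(hi, base)
  expect_lt((hi - lo) / base, 0.1)
})

test_that("the biosimilar discount lowers incremental drug cost linearly", {
  ctx <- make_ctx()
  res0 <- crohncea:::evaluate_context(ctx)
  p40 <- econ_params(biosimilar_discount = 0.40)
  res40 <- crohncea:::evaluate_context(ctx, params = p40)
  d_ada0 <- res0$components["TC", "adalimumab"] -
    res0$components["CM", "adalimumab"]
  d_ada40 <- res40$components["TC", "adalimumab"] -
    res40$components["CM", "adalimumab"]
  expect_equal(d_ada40, 0.6 * d_ada0, tolerance = 1e-9)
})

test_that("tornado rows are sorted by extent and ranges validated", {
  ctx <- make_ctx()
  tor <- run_owsa(ctx)
  expect_true(all(diff(tor$extent) <= 0))
  expect_true("utility_source" %in% tor$parameter)
  one_sided <- tor[tor$parameter == "utility_source", ]
  expect_true(is.na(one_sided$icer_high))
  bad <- econ_params()
  bad$ranges <- list(crp_test = c(16.60, 3.72))
  expect_error(run_owsa(make_ctx(params = bad)), "inverted")
})

test_that("a single-point horizon grid returns the base-case ICER", {
  ctx <- make_ctx(horizon = 260)
  base <- crohncea:::evaluate_context(ctx)
  sweep <- horizon_sweep(ctx, 260)
  expect_equal(sweep$icer, base$direct$delta_cost / base$direct$delta_qaly)
})

test_that("identical arms leave the ICER undefined at every horizon", {
  fit_null <- transition_fit(
    beta = c(lag_moderate = 0.9, lag_severe = 1.7, lag_very_severe = 2.4,
             tc = 0, tc_lag_moderate = 0, tc_lag_severe = 0,
             tc_lag_very_severe = 0, gap_weeks = 0, peak_dummy = 0),
    tau = c(0.5, 1.6, 2.6))
  # same transition law, same flat toll, but TC still pays for monitoring
  # and escalation, so make both zero to get fully identical arms
  params <- econ_params(fcp_test = 0, crp_test = 0,
                        dose_schedule = function(arm, week) 0 * week)
  ctx <- cea_context(fit_null, flat_hosp_fit(0.005), c(0, 0.74, 0.2, 0.06),
                     params, horizon_weeks = 156)
  sweep <- horizon_sweep(ctx, c(48, 104, 156))
  expect_true(all(is.na(sweep$icer)))
  expect_true(all(sweep$label == "UNDEFINED"))
})

test_that("zero covariance degenerates draws to the mean", {
  fit <- toy_fit()
  draws <- draw_correlated_coefficients(fit, n = 7)
  expect_equal(nrow(draws), 7)
  for (i in 1:7) {
    expect_equal(unname(draws[i, ]), unname(c(fit$beta, fit$tau)))
  }
})

test_that("identity covariance gives iid standard-normal draws", {
  d <- 12
  fit <- transition_fit(beta = rep(0, 9), tau = c(-1, 0, 1),
                        cov = diag(d))
  set.seed(101)
  draws <- draw_correlated_coefficients(fit, n = 10000, max_reject = 1e6)
  # thresholds were rejection-sampled for ordering, so moment-check betas only
  m <- colMeans(draws[, 1:9])
  v <- apply(draws[, 1:9], 2, var)
  expect_true(all(abs(m) < 3 / sqrt(10000)))
  expect_true(all(abs(v - 1) < 5 * sqrt(2 / 10000)))
})

test_that("draw covariance matches the fit covariance", {
  set.seed(103)
  A <- matrix(rnorm(16), 4, 4)
  cov <- crossprod(A) / 4
  hf <- hosp_fit(gamma = c(intercept = -2, a = 0.1, b = 0.2, c = 0.3),
                 cov = cov)
  draws <- draw_correlated_coefficients(hf, n = 50000)
  emp <- cov(draws)
  expect_lt(max(abs(emp - cov)), 4 * max(diag(cov)) / sqrt(50000) * 3)
  expect_equal(unname(colMeans(draws)), unname(hf$gamma), tolerance = 0.05)
})

test_that("threshold-ordering violations are rejected and redrawn", {
  d <- 12
  fit <- transition_fit(beta = rep(0, 9), tau = c(-0.01, 0, 0.01),
                        cov = diag(d))
  set.seed(107)
  expect_message(draws <- draw_correlated_coefficients(fit, n = 200,
                                                       max_reject = 1e6),
                 "rejected")
  tau_draws <- draws[, 10:12]
  expect_true(all(apply(tau_draws, 1, function(t) all(diff(t) > 0))))
})

test_that("PSA with all uncertainty off reproduces the deterministic result", {
  ctx <- make_ctx()
  det <- crohncea:::evaluate_context(ctx)
  psa <- run_psa(ctx, n_draws = 5, seed = 3, cost_cv = 0,
                 utility_cv = 0, coef_uncertainty = FALSE)
  for (i in 1:5) {
    expect_equal(psa$draws$delta_cost_direct[i], det$direct$delta_cost)
    expect_equal(psa$draws$delta_qaly[i], det$direct$delta_qaly)
    expect_equal(psa$draws$delta_cost_with_absenteeism[i],
                 det$with_absenteeism$delta_cost)
  }
})

test_that("the same seed reproduces the PSA draw table exactly", {
  fit <- toy_fit()
  fit$cov <- diag(12) * 1e-3
  ctx <- cea_context(fit, flat_hosp_fit(0.005), c(0, 0.74, 0.2, 0.06),
                     econ_params(), horizon_weeks = 104)
  p1 <- run_psa(ctx, n_draws = 25, seed = 11)
  p2 <- run_psa(ctx, n_draws = 25, seed = 11)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(ctx, n_draws = 25, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("CEAC equals a brute-force recount of the stored draws", {
  ctx <- make_ctx(horizon = 104)
  psa <- run_psa(ctx, n_draws = 60, seed = 13)
  grid <- seq(0, 100000, by = 12500)
  curve <- ceac(psa, grid)
  for (j in seq_along(grid)) {
    lam <- grid[j]
    count <- 0
    for (i in seq_len(nrow(psa$draws))) {
      if (lam * psa$draws$delta_qaly[i] - psa$draws$delta_cost_direct[i] > 0) {
        count <- count + 1
      }
    }
    expect_identical(curve$p_ce_direct[j], count / nrow(psa$draws))
  }
  # lambda = 0: fraction of cost-saving draws
  expect_equal(curve$p_ce_direct[1], mean(psa$draws$delta_cost_direct < 0))
})

test_that("dominant draws give probability one at every threshold", {
  psa <- structure(list(draws = data.frame(
    draw = 1:4, delta_cost_direct = c(-10, -5, -1, -20),
    delta_cost_with_absenteeism = c(-15, -8, -2, -30),
    delta_qaly = c(0.1, 0.2, 0.05, 0.3)), n_draws = 4, seed = 1),
    class = "psa_draws")
  curve <- ceac(psa, c(0, 25000, 50000, 100000))
  expect_true(all(curve$p_ce_direct == 1))
  expect_true(all(curve$p_ce_with_absenteeism == 1))
})
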