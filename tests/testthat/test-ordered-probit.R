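test_that("cell probabilities follow the ordered-probit link", {
  # eta = 0, tau = (-1, 0, 1): P(2) = pnorm(0) - pnorm(-1)
  expect_equal(ordered_probit_cell(0, 2, 0, c(-1, 0, 1)),
               pnorm(0) - pnorm(-1), tolerance = 1e-12)
  expect_equal(ordered_probit_cell(0, 2, 0, c(-1, 0, 1)), 0.3413,
               tolerance = 1e-3)
})

test_that("cell probabilities telescope to one and respect symmetry", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(3)
    beta <- rnorm(3)
    tau <- sort(rnorm(3))
    probs <- vapply(1:4, ordered_probit_cell, numeric(1),
                    x = x, beta = beta, tau = tau)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
  # symmetric thresholds at eta = 0: P(1) = P(4), P(2) = P(3)
  a <- 0.7
  probs <- vapply(1:4, ordered_probit_cell, numeric(1),
                  x = 0, beta = 0, tau = c(-a, 0, a))
  expect_equal(probs[1], probs[4], tolerance = 1e-12)
  expect_equal(probs[2], probs[3], tolerance = 1e-12)
})

test_that("non-monotone thresholds are rejected", {
  expect_error(ordered_probit_cell(0, 1, 0, c(1, 0, 2)), "increasing")
  expect_error(transition_fit(beta = rep(0, 9), tau = c(1, 1, 2)),
               "increasing")
})

test_that("maximum-likelihood fit matches the independent polr oracle", {
  skip_if_not_installed("MASS")
  beta <- default_true_beta()
  tau <- c(0.6, 2.0, 3.0)
  design <- simulate_design(3000, beta, tau, seed = 41)
  fit <- fit_ordered_probit(design)
  X <- crohncea:::design_matrix(design)
  df <- data.frame(y = design$response_state, X)
  oracle <- MASS::polr(y ~ ., data = df, method = "probit", Hess = TRUE)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(unname(fit$tau), unname(oracle$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  # standard errors from the observed information agree too
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-2)
})

test_that("likelihood at the optimum is at least the likelihood at truth", {
  beta <- default_true_beta()
  tau <- c(0.6, 2.0, 3.0)
  design <- simulate_design(1500, beta, tau, seed = 43)
  fit <- fit_ordered_probit(design)
  X <- crohncea:::design_matrix(design)
  y <- as.integer(design$response_state)
  ll_truth <- -crohncea:::op_negloglik(c(beta, tau), X, y, 4)
  expect_gte(fit$loglik, ll_truth)
})

test_that("refitting identical rows is bit-identical", {
  design <- simulate_design(800, default_true_beta(), c(0.6, 2, 3), seed = 47)
  f1 <- fit_ordered_probit(design)
  f2 <- fit_ordered_probit(design)
  expect_identical(f1, f2)
})

test_that("a null treatment effect is not spuriously detected", {
  beta <- default_true_beta()
  beta[c("tc", "tc_lag_moderate", "tc_lag_severe",
         "tc_lag_very_severe")] <- 0
  design <- simulate_design(5000, beta, c(0.6, 2, 3), seed = 1001)
  fit <- fit_ordered_probit(design)
  se_tc <- sqrt(diag(fit$cov))[4]
  expect_lt(abs(fit$beta["tc"]), 3 * se_tc)
})

test_that("sparse terminal categories are pooled with a warning", {
  design <- simulate_design(400, default_true_beta(), c(0.6, 2, 3), seed = 59)
  design$response_state[design$response_state == "very_severe"] <- "severe"
  design$response_state <- droplevels(design$response_state)
  design$response_state <- factor(as.character(design$response_state),
                                  levels = state_levels(), ordered = TRUE)
  expect_warning(fit <- fit_ordered_probit(design), "pooling")
  expect_equal(fit$n_cat, 3L)
  expect_true(fit$collapsed)
  P <- transition_matrix(fit, "CM", 2)
  expect_equal(unname(P[, "very_severe"]), rep(0, 4))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
})

test_that("hospitalization probit matches the glm oracle", {
  set.seed(61)
  design <- simulate_design(2500, default_true_beta(), c(0.6, 2, 3),
                            seed = 61)
  gamma <- c(-1.8, 0.3, 0.6, 0.9, -0.3, 0, 0, 0, 0.02, 0)
  X <- cbind(1, crohncea:::design_matrix(design))
  design$hosp_events <- rbinom(nrow(design), 1, pnorm(drop(X %*% gamma)))
  fit <- fit_hosp_probit(design)
  df <- data.frame(y = design$hosp_events, X[, -1])
  oracle <- glm(y ~ ., data = df, family = binomial("probit"))
  expect_equal(unname(fit$gamma), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-2)
})

test_that("constant hospitalization outcomes raise a separation error", {
  design <- simulate_design(100, default_true_beta(), c(0.6, 2, 3), seed = 67)
  design$hosp_events <- 0L
  expect_error(fit_hosp_probit(design), "separation")
})

test_that("fitted per-state risks preserve a severity gradient", {
  set.seed(71)
  design <- simulate_design(5000, default_true_beta(), c(0.6, 2, 3),
                            seed = 71)
  # true risk rises with the lagged state
  p_true <- c(0.02, 0.05, 0.12, 0.2)[crohncea:::state_code(design$lag_state)]
  design$hosp_events <- rbinom(nrow(design), 1, p_true)
  fit <- fit_hosp_probit(design)
  for (arm in c("CM", "TC")) {
    p <- hosp_weekly_prob(fit, arm)
    expect_true(all(diff(p) > 0))
  }
})
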