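#' Ordered-probit cell probability
#'
#' Probability that an ordinal response falls in category `k` under the
#' ordered probit link: `P(k) = pnorm(tau[k] - eta) - pnorm(tau[k-1] - eta)`
#' with `eta = x %*% beta`, `tau[0] = -Inf` and `tau[K] = Inf`.
#'
#' @param x Covariate vector (no intercept; identification lives in `tau`).
#' @param k Category index in `1..(length(tau) + 1)`.
#' @param beta Coefficient vector, same length as `x`.
#' @param tau Strictly increasing threshold vector (length K - 1 for K
#'   categories).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' # with eta = 0 and tau = c(-1, 0, 1), P(category 2) = pnorm(0) - pnorm(-1)
#' ordered_probit_cell(0, 2, 0, c(-1, 0, 1))
ordered_probit_cell <- function(x, k, beta, tau) {
  check_tau(tau)
  eta <- sum(x * beta)
  n_cat <- length(tau) + 1L
  if (k < 1L || k > n_cat) stop("category index out of range", call. = FALSE)
  upper <- if (k == n_cat) Inf else tau[k]
  lower <- if (k == 1L) -Inf else tau[k - 1L]
  stats::pnorm(upper - eta) - stats::pnorm(lower - eta)
}

check_tau <- function(tau) {
  if (length(tau) < 1L || any(diff(tau) <= 0)) {
    stop("`tau` must be strictly increasing", call. = FALSE)
  }
  invisible(tau)
}

# full row of category probabilities for a linear predictor eta (vectorized
# over eta); returns matrix length(eta) x (length(tau)+1)
ordered_probit_probs <- function(eta, tau) {
  cuts <- c(-Inf, tau, Inf)
  cdf <- vapply(cuts, function(t) stats::pnorm(t - eta),
                numeric(length(eta)))
  if (length(eta) == 1L) cdf <- matrix(cdf, nrow = 1L)
  cdf[, -1L, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
}

# --- penalized maximum likelihood machinery -------------------------------

# negative log-likelihood and analytic gradient for the ordered probit with
# parameters theta = c(beta, tau). Ridge penalty on beta only.
op_negloglik <- function(theta, X, y, n_cat, penalty = 0) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  tau <- theta[p + seq_len(n_cat - 1L)]
  if (any(!is.finite(theta)) || any(diff(tau) <= 0)) return(1e10)
  eta <- drop(X %*% beta)
  cuts <- c(-Inf, tau, Inf)
  pr <- stats::pnorm(cuts[y + 1L] - eta) - stats::pnorm(cuts[y] - eta)
  pr <- pmax(pr, 1e-300)
  -sum(log(pr)) + 0.5 * penalty * sum(beta^2)
}

op_gradient <- function(theta, X, y, n_cat, penalty = 0) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  tau <- theta[p + seq_len(n_cat - 1L)]
  eta <- drop(X %*% beta)
  cuts <- c(-Inf, tau, Inf)
  a_up <- cuts[y + 1L] - eta
  a_lo <- cuts[y] - eta
  pr <- pmax(stats::pnorm(a_up) - stats::pnorm(a_lo), 1e-300)
  d_up <- stats::dnorm(a_up)
  d_lo <- stats::dnorm(a_lo)
  # d logL / d eta = (d_lo - d_up) / pr  -> beta gradient via X
  g_beta <- -drop(crossprod(X, (d_lo - d_up) / pr)) + penalty * beta
  g_tau <- numeric(n_cat - 1L)
  for (j in seq_len(n_cat - 1L)) {
    g_tau[j] <- -sum(d_up[y == j] / pr[y == j]) +
      sum(d_lo[y == j + 1L] / pr[y == j + 1L])
  }
  c(g_beta, g_tau)
}

# reparameterized (unconstrained) optimization space: tau1, log-increments
op_to_free <- function(theta, p, n_cat) {
  tau <- theta[p + seq_len(n_cat - 1L)]
  c(theta[seq_len(p)], tau[1L], log(diff(tau)))
}
op_from_free <- function(free, p, n_cat) {
  tau <- cumsum(c(free[p + 1L], exp(free[p + 1L + seq_len(n_cat - 2L)])))
  c(free[seq_len(p)], tau)
}

# solve the penalized MLE; returns theta-hat, loglik, covariance from the
# inverse observed information evaluated numerically at the optimum
op_solve <- function(X, y, n_cat, penalty = 0, maxit = 500, reltol = 1e-12) {
  p <- ncol(X)
  # start: beta = 0, tau from marginal cumulative frequencies
  cum <- cumsum(tabulate(y, n_cat))[seq_len(n_cat - 1L)] / length(y)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  tau0 <- stats::qnorm(cum)
  tau0 <- tau0 + cumsum(c(0, pmax(0, 1e-3 - diff(tau0))))  # enforce increase
  theta0 <- c(rep(0, p), tau0)
  nll_free <- function(free) {
    op_negloglik(op_from_free(free, p, n_cat), X, y, n_cat, penalty)
  }
  gr_free <- function(free) {
    theta <- op_from_free(free, p, n_cat)
    if (any(!is.finite(theta))) return(numeric(length(free)))
    g <- op_gradient(theta, X, y, n_cat, penalty)
    # chain rule for the log-increment parameterization of tau
    g_tau <- g[p + seq_len(n_cat - 1L)]
    g_free_tau <- c(sum(g_tau),
                    if (n_cat > 2L)
                      vapply(seq_len(n_cat - 2L), function(j) {
                        sum(g_tau[(j + 1L):(n_cat - 1L)]) *
                          exp(free[p + 1L + j])
                      }, numeric(1)))
    c(g[seq_len(p)], g_free_tau)
  }
  opt <- stats::optim(op_to_free(theta0, p, n_cat), nll_free, gr_free,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  theta <- op_from_free(opt$par, p, n_cat)
  grad <- op_gradient(theta, X, y, n_cat, penalty)
  gnorm <- max(abs(grad))
  if (opt$convergence != 0 && gnorm > 1e-4) {
    stop(sprintf(
      "ordered probit did not converge (code %d, gradient inf-norm %.3g)",
      opt$convergence, gnorm), call. = FALSE)
  }
  hess <- stats::optimHess(theta, op_negloglik, op_gradient,
                           X = X, y = y, n_cat = n_cat, penalty = penalty)
  cov <- tryCatch(solve(hess), error = function(e) {
    solve(hess + diag(1e-8, nrow(hess)))
  })
  cov <- (cov + t(cov)) / 2
  list(theta = theta, loglik = -op_negloglik(theta, X, y, n_cat, 0),
       cov = cov, gradient_norm = gnorm)
}

# drop all-constant (unidentifiable) columns; returns list(X, keep)
prune_columns <- function(X) {
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning("dropping unidentifiable covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  list(X = X[, keep, drop = FALSE], keep = keep)
}

# re-embed pruned estimates into the full coefficient space with zeros
embed_full <- function(theta, cov, keep, n_extra) {
  p_full <- length(keep)
  idx <- c(which(keep), p_full + seq_len(n_extra))
  full_theta <- numeric(p_full + n_extra)
  full_theta[idx] <- theta
  full_cov <- matrix(0, p_full + n_extra, p_full + n_extra)
  full_cov[idx, idx] <- cov
  list(theta = full_theta, cov = full_cov)
}

#' Fit the ordered-probit transition model
#'
#' Maximum-likelihood estimation of the health-state transition regression:
#' the response visit's state on lagged-state indicators (remission as
#' reference), treatment, treatment-by-lagged-state interactions, the weeks
#' since the last CDAI measurement and the peak-remission dummy. There is no
#' free intercept; it is absorbed into the thresholds.
#'
#' If a terminal response category is empty in the data, severe and very
#' severe responses are pooled (with a warning) and the fit carries three
#' response categories; predictions then assign zero mass to very severe.
#' All-constant covariate columns are dropped with a warning and reported in
#' the fit. If quasi-separation is detected (an unbounded coefficient), the
#' model is refit with an L2 ridge penalty on the slopes.
#'
#' @param design Design table from [build_design()].
#' @param penalty Ridge penalty applied on separation fallback (default
#'   `1e-4`); keeps the covariance finite for probabilistic sensitivity
#'   analysis.
#' @return Object of class `transition_fit`: `beta` (length 9, named), `tau`
#'   (increasing thresholds), `cov` (joint covariance of `c(beta, tau)` from
#'   the inverse observed information), `loglik`, `n_obs`, `n_cat`,
#'   `collapsed`, `dropped` (names of pruned covariates).
#' @export
fit_ordered_probit <- function(design, penalty = 1e-4) {
  X <- design_matrix(design)
  y <- state_code(design$response_state)
  n_cat <- N_STATES
  collapsed <- FALSE
  counts <- tabulate(y, N_STATES)
  if (counts[1L] == 0L) {
    stop("no remission responses observed; transition model unidentifiable",
         call. = FALSE)
  }
  if (counts[4L] == 0L || counts[3L] == 0L) {
    warning("sparse terminal response category: pooling severe/very severe",
            call. = FALSE)
    y[y == 4L] <- 3L
    n_cat <- 3L
    collapsed <- TRUE
    if (all(tabulate(y, 3L) == 0)) stop("degenerate responses", call. = FALSE)
  }
  pr <- prune_columns(X)
  sol <- op_solve(pr$X, y, n_cat, penalty = 0)
  if (max(abs(sol$theta[seq_len(ncol(pr$X))])) > 15) {
    warning("quasi-separation detected; refitting with ridge penalty ",
            penalty, call. = FALSE)
    sol <- op_solve(pr$X, y, n_cat, penalty = penalty)
  }
  emb <- embed_full(sol$theta, sol$cov, pr$keep, n_cat - 1L)
  p <- ncol(X)
  beta <- stats::setNames(emb$theta[seq_len(p)], colnames(X))
  tau <- emb$theta[p + seq_len(n_cat - 1L)]
  transition_fit(beta = beta, tau = tau, cov = emb$cov,
                 loglik = sol$loglik, n_obs = length(y),
                 collapsed = collapsed,
                 dropped = colnames(X)[!pr$keep])
}

#' Construct a transition-model fit object
#'
#' Builds a `transition_fit` directly from coefficients, which lets the
#' Markov engine run on externally specified or ground-truth parameters
#' without estimation.
#'
#' @param beta Named coefficient vector over the transition covariate block
#'   (see [fit_ordered_probit()]).
#' @param tau Strictly increasing thresholds.
#' @param cov Joint covariance of `c(beta, tau)`; defaults to zero (no
#'   parameter uncertainty).
#' @param loglik,n_obs,collapsed,dropped Metadata; optional.
#' @return Object of class `transition_fit`.
#' @export
transition_fit <- function(beta, tau, cov = NULL, loglik = NA_real_,
                           n_obs = NA_integer_, collapsed = FALSE,
                           dropped = character(0)) {
  check_tau(tau)
  d <- length(beta) + length(tau)
  if (is.null(cov)) cov <- matrix(0, d, d)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-8) stop("cov must be symmetric",
                                          call. = FALSE)
  structure(list(beta = beta, tau = tau, cov = cov, loglik = loglik,
                 n_obs = n_obs, n_cat = length(tau) + 1L,
                 collapsed = collapsed, dropped = dropped),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("Ordered-probit transition model (", x$n_cat, " response categories",
      if (x$collapsed) ", severe/very severe pooled", ")\n", sep = "")
  cat("n =", x$n_obs, " log-likelihood =", format(x$loglik), "\n")
  print(round(rbind(estimate = c(x$beta, tau = x$tau),
                    se = sqrt(diag(x$cov))), 4))
  invisible(x)
}

# --- binary probit for hospitalization risk --------------------------------

bp_negloglik <- function(theta, X, y, penalty = 0) {
  eta <- drop(X %*% theta)
  pr <- ifelse(y == 1L, stats::pnorm(eta), stats::pnorm(-eta))
  pr <- pmax(pr, 1e-300)
  -sum(log(pr)) + 0.5 * penalty * sum(theta[-1L]^2)
}

bp_gradient <- function(theta, X, y, penalty = 0) {
  eta <- drop(X %*% theta)
  d <- stats::dnorm(eta)
  pr <- pmax(ifelse(y == 1L, stats::pnorm(eta), stats::pnorm(-eta)), 1e-300)
  w <- ifelse(y == 1L, d / pr, -d / pr)
  g <- -drop(crossprod(X, w))
  g[-1L] <- g[-1L] + penalty * theta[-1L]
  g
}

#' Fit the hospitalization-risk probit
#'
#' Binary probit for the probability of at least one Crohn's-related
#' hospitalization in an inter-visit interval, with the same covariate block
#' as the state-transition regression plus an intercept. The per-interval
#' probability is converted to a weekly probability downstream via
#' `1 - (1 - p)^(1/gap_weeks)`.
#'
#' @param design Design table from [build_design()] (column `hosp_events`
#'   supplies the event counts; any positive count marks the interval).
#' @param penalty Ridge penalty for the separation fallback (default `1e-4`).
#' @return Object of class `hosp_fit`: `gamma` (named coefficients, intercept
#'   first), `cov`, `loglik`, `n_obs`, `gap_ref` (mean observed gap used as
#'   the reference interval when converting to weekly risk).
#' @export
fit_hosp_probit <- function(design, penalty = 1e-4) {
  X <- cbind(intercept = 1, design_matrix(design))
  y <- as.integer(design$hosp_events > 0)
  if (all(y == 0L) || all(y == 1L)) {
    stop("hospitalization outcome is constant (complete separation); ",
         "cannot fit probit", call. = FALSE)
  }
  pr <- prune_columns(X[, -1L, drop = FALSE])
  Xk <- cbind(intercept = 1, pr$X)
  fit1 <- function(pen) {
    theta0 <- c(stats::qnorm(mean(y)), rep(0, ncol(Xk) - 1L))
    opt <- stats::optim(theta0, bp_negloglik, bp_gradient, X = Xk, y = y,
                        penalty = pen, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    grad <- bp_gradient(opt$par, Xk, y, pen)
    if (opt$convergence != 0 && max(abs(grad)) > 1e-4) {
      stop(sprintf(
        "hospitalization probit did not converge (gradient inf-norm %.3g)",
        max(abs(grad))), call. = FALSE)
    }
    opt
  }
  opt <- fit1(0)
  pen_used <- 0
  if (max(abs(opt$par)) > 15) {
    warning("quasi-separation in hospitalization probit; ",
            "refitting with ridge penalty ", penalty, call. = FALSE)
    opt <- fit1(penalty)
    pen_used <- penalty
  }
  hess <- stats::optimHess(opt$par, bp_negloglik, bp_gradient,
                           X = Xk, y = y, penalty = pen_used)
  cov <- tryCatch(solve(hess),
                  error = function(e) solve(hess + diag(1e-8, nrow(hess))))
  cov <- (cov + t(cov)) / 2
  emb <- embed_full(opt$par[-1L], cov[-1L, -1L, drop = FALSE], pr$keep, 0L)
  gamma <- c(intercept = opt$par[1L],
             stats::setNames(emb$theta, colnames(X)[-1L]))
  full_cov <- matrix(0, length(gamma), length(gamma))
  full_idx <- c(1L, 1L + which(pr$keep))
  full_cov[full_idx, full_idx] <- cov
  structure(list(gamma = gamma, cov = full_cov,
                 loglik = -bp_negloglik(opt$par, Xk, y, 0),
                 n_obs = length(y), gap_ref = mean(design$gap_weeks),
                 dropped = colnames(X[, -1L, drop = FALSE])[!pr$keep]),
            class = "hosp_fit")
}

#' Construct a hospitalization-probit fit object directly
#'
#' @param gamma Named coefficient vector, `intercept` first, then the
#'   transition covariate block.
#' @param cov Covariance matrix (defaults to zero).
#' @param gap_ref Reference interval length in weeks for weekly-risk
#'   conversion.
#' @return Object of class `hosp_fit`.
#' @export
hosp_fit <- function(gamma, cov = NULL, gap_ref = 8) {
  d <- length(gamma)
  if (is.null(cov)) cov <- matrix(0, d, d)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  structure(list(gamma = gamma, cov = cov, loglik = NA_real_,
                 n_obs = NA_integer_, gap_ref = gap_ref,
                 dropped = character(0)),
            class = "hosp_fit")
}

#' Serialize a model fit to JSON
#'
#' @param fit A `transition_fit` or `hosp_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
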