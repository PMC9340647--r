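#' CDAI-defined health states
#'
#' The cohort model occupies four ordinal health states defined by Crohn's
#' Disease Activity Index (CDAI) bands. Hospitalization is deliberately *not*
#' a member: it is a toll event that accrues cost without redirecting the
#' occupancy trajectory (see [run_cohort()]).
#'
#' @return Character vector of the four state labels, ordered from least to
#'   most severe.
#' @export
#' @examples
#' state_levels()
state_levels <- function() {
  c("remission", "moderate", "severe", "very_severe")
}

# number of occupancy states
N_STATES <- 4L

#' Map CDAI scores to health states
#'
#' Assigns each CDAI score to one of the four ordinal health states using the
#' half-open bands remission `[0, 150)`, moderate `[150, 300)`, severe
#' `[300, 450)` and very severe `[450, Inf)`.
#'
#' @param cdai Numeric vector of CDAI scores. Must be non-negative and
#'   non-missing; impute (e.g. with [impute_locf()]) before calling.
#' @return Ordered factor with levels [state_levels()], same length as `cdai`.
#' @export
#' @examples
#' state_from_cdai(c(0, 149, 150, 299, 300, 449, 450, 600))
state_from_cdai <- function(cdai) {
  if (!is.numeric(cdai)) {
    stop("`cdai` must be numeric", call. = FALSE)
  }
  if (anyNA(cdai)) {
    stop("`cdai` contains missing values; impute first (see impute_locf)",
         call. = FALSE)
  }
  if (any(cdai < 0)) {
    stop("`cdai` must be non-negative", call. = FALSE)
  }
  idx <- findInterval(cdai, c(0, 150, 300, 450))
  factor(state_levels()[idx], levels = state_levels(), ordered = TRUE)
}

# integer state codes 1..4 from either a factor, label vector or code vector
state_code <- function(state) {
  if (is.numeric(state)) {
    code <- as.integer(state)
  } else {
    code <- match(as.character(state), state_levels())
  }
  if (anyNA(code) || any(code < 1L | code > N_STATES)) {
    stop("invalid health state", call. = FALSE)
  }
  code
}

# CDAI band edges; the top band is unbounded, capped for uniform draws
state_cdai_bounds <- function(upper_cap = 600) {
  cbind(lower = c(0, 150, 300, 450),
        upper = c(150, 300, 450, upper_cap))
}
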