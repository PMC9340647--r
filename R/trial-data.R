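#' Read a long-format trial observation table
#'
#' Expects a CSV with columns `patient_id`, `arm` (`"TC"` or `"CM"`), `week`,
#' `cdai`, `hosp_events`, `absenteeism_frac`. Empty cells are missing values.
#' Validates the structural invariants: strictly increasing weeks within
#' patient and a constant arm label per patient.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of trial observations, ordered by patient and week.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_trial(df)
}

#' @keywords internal
validate_trial <- function(df) {
  required <- c("patient_id", "arm", "week", "cdai", "hosp_events",
                "absenteeism_frac")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$arm %in% c("TC", "CM"))) {
    stop("`arm` must be 'TC' or 'CM'", call. = FALSE)
  }
  df <- df[order(df$patient_id, df$week), , drop = FALSE]
  by_pat <- split(df, df$patient_id)
  for (pd in by_pat) {
    if (anyDuplicated(pd$week)) {
      stop("duplicate visit weeks for patient ", pd$patient_id[1],
           call. = FALSE)
    }
    if (length(unique(pd$arm)) != 1L) {
      stop("arm changes within patient ", pd$patient_id[1], call. = FALSE)
    }
  }
  if (any(df$week < 0)) stop("`week` must be non-negative", call. = FALSE)
  rownames(df) <- NULL
  df
}

# last-observation-carried-forward on a single numeric vector; leading NAs stay
locf_vector <- function(x) {
  zoo::na.locf(x, na.rm = FALSE)
}

#' Last-observation-carried-forward imputation of CDAI
#'
#' Replaces every missing (or censored) CDAI value with the most recent
#' observed value for the same patient, the standard LOCF treatment of
#' missing longitudinal scores under an intent-to-treat analysis. Patients
#' whose *baseline* CDAI is missing cannot be carried forward from anything
#' and are excluded with a logged reason rather than silently dropped.
#'
#' LOCF is idempotent and never alters an observed value.
#'
#' @param trial Trial observation table (see [read_trial_csv()]).
#' @param log_file Optional path; if given, the exclusion log is written there
#'   as CSV.
#' @return List with elements `data` (the imputed table, excluded patients
#'   removed) and `excluded` (a `data.frame` with columns `patient_id`,
#'   `reason`; zero rows when nothing was excluded).
#' @export
#' @examples
#' trial <- data.frame(
#'   patient_id = "p1", arm = "CM", week = c(0, 2, 6),
#'   cdai = c(200, NA, 310), hosp_events = 0, absenteeism_frac = NA
#' )
#' impute_locf(trial)$data$cdai  # 200 200 310
impute_locf <- function(trial, log_file = NULL) {
  trial <- validate_trial(trial)
  excluded <- data.frame(patient_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  pieces <- split(trial, trial$patient_id)
  kept <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    pd <- pieces[[i]]
    if (all(is.na(pd$cdai))) {
      excluded <- rbind(excluded, data.frame(
        patient_id = pd$patient_id[1], reason = "all CDAI values missing",
        stringsAsFactors = FALSE))
      next
    }
    if (is.na(pd$cdai[1])) {
      excluded <- rbind(excluded, data.frame(
        patient_id = pd$patient_id[1], reason = "baseline CDAI missing",
        stringsAsFactors = FALSE))
      next
    }
    pd$cdai <- locf_vector(pd$cdai)
    kept[[i]] <- pd
  }
  if (nrow(excluded) > 0) {
    warning(nrow(excluded), " patient(s) excluded during LOCF imputation",
            call. = FALSE)
  }
  if (!is.null(log_file)) {
    utils::write.csv(excluded, log_file, row.names = FALSE)
  }
  out <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  rownames(out) <- NULL
  list(data = out, excluded = excluded)
}

#' Build the transition regression design
#'
#' Turns an imputed trial table into one design row per consecutive visit
#' pair per patient: the response is the health state at the later visit,
#' regressed on the lagged state, treatment arm, treatment-by-lagged-state
#' interactions, the gap in weeks since the last CDAI measurement, and a
#' dummy marking the visit window of peak clinical remission (used to
#' stabilise extrapolation beyond the trial follow-up).
#'
#' @param trial Imputed trial table (no missing CDAI; see [impute_locf()]).
#' @param peak_weeks Integer vector of visit weeks whose *response* visit gets
#'   `peak_dummy = 1`. Default `11`, the visit at which clinical remission
#'   peaks under the default schedule; configurable because the choice is an
#'   assumption.
#' @return A `data.frame` with one row per transition: `patient_id`, `arm`,
#'   `week`, `response_state`, `lag_state`, `treatment` (1 = TC),
#'   `gap_weeks`, `peak_dummy`.
#' @export
build_design <- function(trial, peak_weeks = 11) {
  trial <- validate_trial(trial)
  if (anyNA(trial$cdai)) {
    stop("trial table has missing CDAI; run impute_locf first", call. = FALSE)
  }
  trial$state <- state_from_cdai(trial$cdai)
  pieces <- split(trial, trial$patient_id)
  rows <- lapply(pieces, function(pd) {
    n <- nrow(pd)
    if (n < 2L) return(NULL)
    data.frame(
      patient_id = pd$patient_id[-1],
      arm = pd$arm[-1],
      week = pd$week[-1],
      response_state = pd$state[-1],
      lag_state = pd$state[-n],
      treatment = as.integer(pd$arm[-1] == "TC"),
      gap_weeks = diff(pd$week),
      peak_dummy = as.integer(pd$week[-1] %in% peak_weeks),
      hosp_events = pd$hosp_events[-1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Model matrix shared by the ordered probit (no intercept; identification is
# absorbed into the thresholds) and, with an added intercept, the
# hospitalization probit. Remission is the reference lagged state.
design_matrix <- function(design) {
  lag <- state_code(design$lag_state)
  tc <- design$treatment
  X <- cbind(
    lag_moderate = as.numeric(lag == 2L),
    lag_severe = as.numeric(lag == 3L),
    lag_very_severe = as.numeric(lag == 4L),
    tc = tc,
    tc_lag_moderate = tc * (lag == 2L),
    tc_lag_severe = tc * (lag == 3L),
    tc_lag_very_severe = tc * (lag == 4L),
    gap_weeks = design$gap_weeks,
    peak_dummy = design$peak_dummy
  )
  X
}

# covariate row for prediction at a given (lag state, arm, gap, peak)
covariate_row <- function(lag_state, treatment, gap_weeks, peak_dummy) {
  design_matrix(data.frame(
    lag_state = lag_state, treatment = treatment,
    gap_weeks = gap_weeks, peak_dummy = peak_dummy
  ))[1, ]
}
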