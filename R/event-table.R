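#' Validate a longitudinal dosing/observation event table
#'
#' Event tables follow the de-facto rectangular layout of nonlinear
#' mixed-effects PK software: one row per event with columns
#' `ID` (subject), `TIME` (h), `EVID` (1 = dose, 0 = observation),
#' `AMT` (dose amount, mg; `NA` on observation rows), `DV` (observed
#' concentration, ng/ml; `NA` on dose rows), plus per-subject covariate
#' columns (at minimum `WT`, body weight in kg, and `FLU`, the fluoxetine
#' flag).
#'
#' Checked invariants: times are non-negative and non-decreasing within
#' subject; every subject has at least one dose row; observation `DV`
#' values are non-negative (when supplied); dose rows carry `AMT` and no
#' `DV`; observation rows carry `DV` and no `AMT`; covariates are constant
#' within subject.
#'
#' @param data A data frame of events.
#' @return `data` as a tibble, invisibly sorted checks aside; errors list
#'   every violated invariant.
#' @examples
#' spec <- cohort_spec(n_subjects = 4)
#' tab <- generate_cohort(spec, final_model_params(), seed = 1)
#' validate_event_table(tab)
#' @export
validate_event_table <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("ID", "TIME", "EVID", "AMT", "DV", "WT", "FLU")
  missing_cols <- setdiff(required, names(data))
  problems <- character()
  if (length(missing_cols)) {
    stop("event table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(data$TIME < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative TIME values")
  }
  if (!all(data$EVID %in% c(0, 1))) {
    problems <- c(problems, "EVID must be 0 (observation) or 1 (dose)")
  }
  bad_dose_dv <- which(data$EVID == 1 & !is.na(data$DV))
  if (length(bad_dose_dv)) {
    problems <- c(problems, paste0("DV present on dose row(s): ",
                                   paste(utils::head(bad_dose_dv, 5), collapse = ", ")))
  }
  if (any(data$EVID == 1 & is.na(data$AMT))) {
    problems <- c(problems, "dose row(s) without AMT")
  }
  if (any(data$EVID == 0 & is.na(data$DV))) {
    problems <- c(problems, "observation row(s) without DV")
  }
  if (any(data$EVID == 0 & !is.na(data$AMT))) {
    problems <- c(problems, "AMT present on observation row(s)")
  }
  if (any(data$DV < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative observed concentration(s)")
  }
  by_id <- split(data, data$ID)
  if (any(vapply(by_id, function(d) is.unsorted(d$TIME), logical(1)))) {
    problems <- c(problems, "TIME not non-decreasing within subject")
  }
  if (any(vapply(by_id, function(d) !any(d$EVID == 1), logical(1)))) {
    problems <- c(problems, "subject(s) without any dose row")
  }
  cov_cols <- setdiff(names(data), c("ID", "TIME", "EVID", "AMT", "DV"))
  varying <- vapply(by_id, function(d) {
    any(vapply(cov_cols, function(cc) length(unique(d[[cc]])) > 1L, logical(1)))
  }, logical(1))
  if (any(varying)) {
    problems <- c(problems, "covariate(s) vary within subject")
  }
  if (length(problems)) {
    stop("invalid event table:\n  - ", paste(problems, collapse = "\n  - "))
  }
  data
}

#' Read an event table from a delimited file
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A validated event-table tibble.
#' @seealso [write_event_table()], [validate_event_table()]
#' @export
read_event_table <- function(path, delim = ",") {
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE, na = c("", "NA", "."))
  validate_event_table(data)
}

#' Write an event table to a delimited file
#'
#' Round-trips through [read_event_table()].
#'
#' @param data An event table.
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_event_table <- function(data, path, delim = ",") {
  validate_event_table(data)
  readr::write_delim(data, path, delim = delim, na = "NA")
  invisible(path)
}

# Summary helpers ------------------------------------------------------------

#' Per-subject covariate table of an event table
#'
#' @param data An event table.
#' @return One row per subject with ID and the subject-constant covariates.
#' @export
subject_covariates <- function(data) {
  cov_cols <- setdiff(names(data), c("TIME", "EVID", "AMT", "DV"))
  dplyr::distinct(dplyr::select(tibble::as_tibble(data),
                                dplyr::all_of(cov_cols)))
}
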