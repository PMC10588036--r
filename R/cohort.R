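#' Survival cohort construction and validation
#'
#' A survival cohort is a plain `data.frame` with one row per subject and at
#' least the columns `subject_id`, `time` (follow-up in years, strictly
#' positive), and `event` (0/1). Any further numeric columns are treated as
#' covariates (binary covariates coded 0/1). The class attribute
#' `"survival_cohort"` marks a validated table.
#'
#' @param data data.frame with columns `subject_id`, `time`, `event` and
#'   numeric covariates.
#' @return `data` with class `survival_cohort` prepended, after validation.
#' @examples
#' co <- as_survival_cohort(data.frame(
#'   subject_id = 1:4, time = c(1, 2, 3, 4), event = c(1, 0, 1, 0),
#'   age = c(60, 70, 65, 72)))
#' @export
as_survival_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  needed <- c("subject_id", "time", "event")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$subject_id)) {
    stop("duplicated subject_id values", call. = FALSE)
  }
  bad_time <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad_time) > 0) {
    stop("validation error: non-positive or non-finite time in row(s): ",
         paste(utils::head(bad_time, 10), collapse = ", "), call. = FALSE)
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("event must be coded 0/1", call. = FALSE)
  }
  class(data) <- unique(c("survival_cohort", class(data)))
  data
}

#' Read a cohort table from delimited text
#'
#' Reads a comma-separated file with a header row into a validated survival
#' cohort. A `schema` can rename columns and recode the event indicator
#' (e.g. `yes`/`no` to 1/0). Unparseable numeric cells become `NA` and a
#' per-column count of coerced cells is reported as a warning.
#'
#' @param path path to a CSV file (header row, "." decimal).
#' @param schema optional list with elements `time`, `event`, `subject_id`
#'   giving the source column names, and `event_codes`, a named vector
#'   mapping source codes to 0/1 (names = source values).
#' @return a `survival_cohort` data.frame.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rename <- function(df, from, to) {
    if (!is.null(from)) {
      if (!from %in% names(df)) {
        stop("schema error: declared column '", from, "' not found",
             call. = FALSE)
      }
      names(df)[names(df) == from] <- to
    }
    df
  }
  raw <- rename(raw, schema$subject_id, "subject_id")
  raw <- rename(raw, schema$time, "time")
  raw <- rename(raw, schema$event, "event")
  missing_cols <- setdiff(c("time", "event"), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"subject_id" %in% names(raw)) raw$subject_id <- seq_len(nrow(raw))
  if (!is.null(schema$event_codes)) {
    raw$event <- unname(schema$event_codes[as.character(raw$event)])
  }
  # coerce covariates to numeric, counting cells lost per column
  keep_chr <- "arm"
  for (cn in setdiff(names(raw), c("subject_id", keep_chr))) {
    if (!is.numeric(raw[[cn]])) {
      coerced <- suppressWarnings(as.numeric(raw[[cn]]))
      n_bad <- sum(is.na(coerced) & !is.na(raw[[cn]]))
      if (n_bad > 0) {
        warning(sprintf("column '%s': %d unparseable cell(s) set to NA",
                        cn, n_bad), call. = FALSE)
      }
      raw[[cn]] <- coerced
    }
  }
  as_survival_cohort(raw)
}

#' Write a cohort table as delimited text
#'
#' @param cohort a `survival_cohort`.
#' @param path output CSV path (header row, "." decimal, UTF-8).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# internal: numeric covariate column names of a cohort
cohort_covariates <- function(cohort) {
  setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
          c("subject_id", "time", "event"))
}
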