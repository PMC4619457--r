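read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(label, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

parse_date_col <- function(x, col, label) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop(label, ": unparseable ", col, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

parse_num_col <- function(x, col, label, positive = TRUE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | (positive & out <= 0))
  if (length(bad) > 0L) {
    stop(label, ": invalid ", col, " (must be a positive number) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read and validate the pipeline input files
#'
#' CSV dialects: `dispensing.csv` (`patient_id`, `atc_code`,
#' `dispense_date`, `units_dispensed`, `daily_number`), `followup.csv`
#' (`patient_id`, `entry_date`, `exit_date`, `exit_reason`), and
#' `gp_events.csv` (`patient_id`, `event_date`, `adjudication_code`,
#' optional `adr_term`). Dates are ISO-8601. Validation errors name the
#' offending rows; referential integrity (every dispensing/event patient
#' has a follow-up record) is enforced by [check_cohort_integrity()].
#'
#' @param path Path to the CSV file.
#' @return A typed data.frame.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_dispensing <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "atc_code", "dispense_date",
                                 "units_dispensed", "daily_number"),
                         "dispensing")
  if (any(!nzchar(df$atc_code))) {
    stop("dispensing: empty atc_code at row(s) ",
         paste(utils::head(which(!nzchar(df$atc_code)), 5L),
               collapse = ", "), call. = FALSE)
  }
  data.frame(patient_id = df$patient_id, atc_code = df$atc_code,
             dispense_date = parse_date_col(df$dispense_date,
                                            "dispense_date", "dispensing"),
             units_dispensed = parse_num_col(df$units_dispensed,
                                             "units_dispensed", "dispensing"),
             daily_number = parse_num_col(df$daily_number, "daily_number",
                                          "dispensing"),
             stringsAsFactors = FALSE)
}

#' @rdname read_inputs
#' @export
read_followup <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "entry_date", "exit_date",
                                 "exit_reason"), "followup")
  entry <- parse_date_col(df$entry_date, "entry_date", "followup")
  exit <- parse_date_col(df$exit_date, "exit_date", "followup")
  bad <- which(entry >= exit)
  if (length(bad) > 0L) {
    stop("followup: entry_date must precede exit_date at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  ok <- df$exit_reason %in% c("END_OF_STUDY", "MOVED_OUT", "DEATH")
  if (any(!ok)) {
    stop("followup: unknown exit_reason at row(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("followup: duplicated patient_id", call. = FALSE)
  }
  data.frame(patient_id = df$patient_id, entry_date = entry,
             exit_date = exit, exit_reason = df$exit_reason,
             stringsAsFactors = FALSE)
}

#' @rdname read_inputs
#' @export
read_gp_events <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "event_date",
                                 "adjudication_code"), "gp_events")
  ok <- df$adjudication_code %in% gp_event_codes()
  if (any(!ok)) {
    stop("gp_events: unknown adjudication_code at row(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  term <- if ("adr_term" %in% names(df)) {
    ifelse(nzchar(df$adr_term), df$adr_term, NA_character_)
  } else rep(NA_character_, nrow(df))
  misplaced <- !is.na(term) &
    !(df$adjudication_code %in% c("DEFINITE_ADR", "PROBABLE_ADR"))
  if (any(misplaced)) {
    stop("gp_events: adr_term only allowed for DEFINITE_ADR/PROBABLE_ADR, ",
         "row(s) ", paste(utils::head(which(misplaced), 5L), collapse = ", "),
         call. = FALSE)
  }
  data.frame(patient_id = df$patient_id,
             event_date = parse_date_col(df$event_date, "event_date",
                                         "gp_events"),
             adjudication_code = df$adjudication_code, adr_term = term,
             stringsAsFactors = FALSE)
}

#' Check referential integrity of a cohort
#'
#' Every dispensing and GP-event patient must have a follow-up record, and
#' dispensings and events must fall within the patient's follow-up.
#'
#' @param dispensing,followup,gp_events Typed data frames as returned by
#'   the `read_*` functions or [generate_cohort()].
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
check_cohort_integrity <- function(dispensing, followup, gp_events = NULL) {
  orphan <- setdiff(unique(dispensing$patient_id), followup$patient_id)
  if (length(orphan) > 0L) {
    stop("dispensing for patient(s) without follow-up record: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(gp_events)) {
    orphan <- setdiff(unique(gp_events$patient_id), followup$patient_id)
    if (length(orphan) > 0L) {
      stop("gp_events for patient(s) without follow-up record: ",
           paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
    }
  }
  at <- match(dispensing$patient_id, followup$patient_id)
  out <- dispensing$dispense_date < followup$entry_date[at] |
    dispensing$dispense_date > followup$exit_date[at]
  if (any(out)) {
    stop("dispensing outside follow-up at row(s) ",
         paste(utils::head(which(out), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a generated cohort to CSV files
#'
#' Writes `dispensing.csv`, `followup.csv`, `gp_events.csv` and
#' `ground_truth.csv` in the documented dialects (ISO-8601 dates), such
#' that reading them back with the `read_*` functions round-trips the
#' records.
#'
#' @param cohort List as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("dispensing.csv", "followup.csv",
                            "gp_events.csv", "ground_truth.csv"))
  utils::write.csv(cohort$dispensing, paths[1L], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$followup, paths[2L], row.names = FALSE, na = "")
  utils::write.csv(cohort$gp_events, paths[3L], row.names = FALSE, na = "")
  utils::write.csv(cohort$ground_truth, paths[4L], row.names = FALSE,
                   na = "")
  invisible(paths)
}
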