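# precedence used when several events fall in an evaluation window:
# a clearly attributed ADR dominates, an explicit non-ADR reason dominates
# speculative mentions
adjudication_precedence <- function() {
  c("DEFINITE_ADR", "DEFINITE_NON_ADR", "PROBABLE_ADR", "NON_PROBABLE_HP")
}

adjudicate_window <- function(events, window_start, window_end) {
  if (is.null(events) || nrow(events) == 0L) {
    hit <- events[integer(0), , drop = FALSE]
  } else {
    d <- events$event_date
    hit <- events[d >= window_start & d <= window_end, , drop = FALSE]
  }
  cls <- "NOTHING_MENTIONED"
  term <- NA_character_
  for (code in adjudication_precedence()) {
    sel <- hit$adjudication_code == code
    if (any(sel)) {
      cls <- code
      if (code %in% c("DEFINITE_ADR", "PROBABLE_ADR")) {
        sub <- hit[sel, , drop = FALSE]
        term <- sub$adr_term[order(sub$event_date)][1L]
      }
      break
    }
  }
  list(patient_class = cls, adr_term = term,
       window_start = window_start, window_end = window_end)
}

#' Adjudicate a test-positive patient from coded medical-record events
#'
#' Scans the closed window from `before_days` before to `after_days` after
#' the index (switch/stop) date. The patient-level class is the
#' highest-precedence code among events in the window
#' (`DEFINITE_ADR > DEFINITE_NON_ADR > PROBABLE_ADR > NON_PROBABLE_HP`), or
#' `NOTHING_MENTIONED` when no event falls inside. The supporting ADR term
#' is taken from the earliest event carrying the winning code.
#'
#' @param events Data frame of the patient's coded events: `patient_id`,
#'   `event_date`, `adjudication_code`, optional `adr_term`.
#' @param index_date The switch or stop date.
#' @param before_days,after_days Window half-widths in days (defaults 180
#'   and 90: six months before, three months after).
#' @return One-row data.frame: `patient_class`, `adr_term`, `window_start`,
#'   `window_end`.
#' @export
adjudicate_case <- function(events, index_date, before_days = 180L,
                            after_days = 90L) {
  index_date <- as_date(index_date, "index_date")
  res <- adjudicate_window(events, index_date - before_days,
                           index_date + after_days)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Adjudicate a continuation (test-negative) patient over a matched duration
#'
#' For sensitivity/specificity the records of a matched continuer are
#' searched from the ACEI start date for the same duration the matched case
#' used the ACEI; the same precedence logic applies over the closed window
#' `[start, start + duration]`.
#'
#' @inheritParams adjudicate_case
#' @param acei_start_date The continuer's first ACEI dispensing date.
#' @param duration_days Non-negative matched evaluation duration.
#' @return One-row data.frame as for [adjudicate_case()].
#' @export
adjudicate_control <- function(events, acei_start_date, duration_days) {
  if (duration_days < 0) stop("duration_days must be >= 0", call. = FALSE)
  acei_start_date <- as_date(acei_start_date, "acei_start_date")
  res <- adjudicate_window(events, acei_start_date,
                           acei_start_date + duration_days)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Is a patient class counted at a given ascertainment level?
#'
#' Levels are nested: `DEFINITE` counts only `DEFINITE_ADR`;
#' `AT_LEAST_PROBABLE` adds `PROBABLE_ADR`; `AT_LEAST_POSSIBLE` adds
#' `NOTHING_MENTIONED` (records silent on the discontinuation leave an ADR
#' possible). `DEFINITE_NON_ADR` and `NON_PROBABLE_HP` belong to no level.
#'
#' @param patient_class Character vector of patient classes.
#' @param level One of [ascertainment_levels()].
#' @return Logical vector.
#' @export
in_level <- function(patient_class, level) {
  level <- match.arg(level, ascertainment_levels())
  members <- switch(level,
    DEFINITE = "DEFINITE_ADR",
    AT_LEAST_PROBABLE = c("DEFINITE_ADR", "PROBABLE_ADR"),
    AT_LEAST_POSSIBLE = c("DEFINITE_ADR", "PROBABLE_ADR",
                          "NOTHING_MENTIONED"))
  patient_class %in% members
}

#' Adjudicate a whole classified cohort
#'
#' Test-positive patients (stop/switch) are adjudicated in the window around
#' their index date; continuers are adjudicated over their entire ACEI
#' episode, `[acei_start_date, acei_start_date + acei_duration_days]`.
#'
#' @param patterns Data frame from [classify_patterns()].
#' @param events Data frame of coded GP events for the cohort.
#' @inheritParams adjudicate_case
#' @return Data frame with one row per pattern row: `patient_id`,
#'   `patient_class`, `adr_term`, `window_start`, `window_end`.
#' @export
adjudicate_cohort <- function(patterns, events, before_days = 180L,
                              after_days = 90L) {
  ev_idx <- split(seq_len(nrow(events)), events$patient_id)
  ev_day <- as.integer(as_date(events$event_date, "event_date"))
  ev_rank <- match(events$adjudication_code, adjudication_precedence())
  ev_term <- if ("adr_term" %in% names(events)) events$adr_term
    else rep(NA_character_, nrow(events))
  n <- nrow(patterns)
  cls <- rep("NOTHING_MENTIONED", n); term <- rep(NA_character_, n)
  positive <- patterns$category %in% test_positive_categories()
  ws <- ifelse(positive, as.integer(patterns$index_date) - before_days,
               as.integer(patterns$acei_start_date))
  we <- ifelse(positive, as.integer(patterns$index_date) + after_days,
               as.integer(patterns$acei_start_date) +
                 patterns$acei_duration_days)
  at <- ev_idx[patterns$patient_id]
  for (k in seq_len(n)) {
    i <- at[[k]]
    if (is.null(i)) next
    i <- i[ev_day[i] >= ws[k] & ev_day[i] <= we[k]]
    if (length(i) == 0L) next
    r <- min(ev_rank[i])
    cls[k] <- adjudication_precedence()[r]
    if (r == 1L || r == 3L) {       # definite or probable ADR carries a term
      j <- i[ev_rank[i] == r]
      term[k] <- ev_term[j[which.min(ev_day[j])]]
    }
  }
  data.frame(patient_id = patterns$patient_id, patient_class = cls,
             adr_term = term,
             window_start = as.Date(ws, origin = "1970-01-01"),
             window_end = as.Date(we, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}
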