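#' Theoretical end date of a prescription
#'
#' The day a dispensed supply runs out: dispense date plus the number of
#' units dispensed divided by the prescribed daily number, rounded half-up
#' to whole days with a minimum coverage of one day. The end date is
#' half-open: it is the first day no longer covered.
#'
#' @param dispense_date Date (or coercible) vector of dispensing dates.
#' @param units_dispensed Positive numeric vector, units per dispensing.
#' @param daily_number Positive numeric vector, prescribed units per day.
#' @return Date vector of theoretical end dates.
#' @examples
#' prescription_end(as.Date("2000-01-01"), 90, 1)   # 2000-03-31
#' prescription_end(as.Date("2000-01-01"), 30, 2)   # 2000-01-16
#' @export
prescription_end <- function(dispense_date, units_dispensed, daily_number) {
  dispense_date <- as_date(dispense_date, "dispense_date")
  if (any(!is.finite(units_dispensed)) || any(units_dispensed <= 0)) {
    stop("units_dispensed must be positive", call. = FALSE)
  }
  if (any(!is.finite(daily_number)) || any(daily_number <= 0)) {
    stop("daily_number must be positive", call. = FALSE)
  }
  # round half-up (base round() is round-half-even), floor of at least 1 day
  duration <- pmax(1, floor(units_dispensed / daily_number + 0.5))
  dispense_date + duration
}

#' Identify ACEI starters (new users)
#'
#' A patient is a starter when the first-ever ACEI dispensing falls on or
#' after `study_start`, database follow-up covers at least `lookback_days`
#' before it, and no ACEI was dispensed within that lookback. Because the
#' check uses the first dispensing on record, any earlier ACEI history also
#' excludes the patient.
#'
#' @param dispensing Data frame of dispensing records with columns
#'   `patient_id`, `atc_code`, `dispense_date`, `units_dispensed`,
#'   `daily_number`.
#' @param followup Data frame with `patient_id`, `entry_date`, `exit_date`,
#'   `exit_reason`.
#' @param study_start Date; inclusion window start (default 2000-01-01).
#' @param lookback_days Integer; required ACEI-free, covered history before
#'   the first dispensing (default 182, i.e. six months).
#' @param class_map ATC prefix map, see [atc_class_map()].
#' @return Data frame with `patient_id` and `first_acei_date` for included
#'   starters.
#' @export
identify_starters <- function(dispensing, followup,
                              study_start = as.Date("2000-01-01"),
                              lookback_days = 182L,
                              class_map = atc_class_map()) {
  study_start <- as_date(study_start, "study_start")
  orphan <- setdiff(unique(dispensing$patient_id), followup$patient_id)
  if (length(orphan) > 0L) {
    stop("dispensing records without follow-up record for patient(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  cls <- classify_atc(dispensing$atc_code, class_map)
  acei <- dispensing[!is.na(cls) & cls == "ACEI", , drop = FALSE]
  if (nrow(acei) == 0L) {
    return(data.frame(patient_id = character(0),
                      first_acei_date = as.Date(character(0))))
  }
  d <- as_date(acei$dispense_date, "dispense_date")
  first <- tapply(as.integer(d), acei$patient_id, min)
  first_date <- as.Date(as.integer(first), origin = "1970-01-01")
  ids <- names(first)
  entry <- followup$entry_date[match(ids, followup$patient_id)]
  keep <- first_date >= study_start & entry <= first_date - lookback_days
  out <- data.frame(patient_id = ids[keep],
                    first_acei_date = first_date[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Build the ACEI treatment episode for one patient
#'
#' Starting from the first dispensing, each later dispensing is chained into
#' the episode if it occurs no more than `gap_days` after the running
#' theoretical end of supply; the episode end is the running maximum of
#' chained theoretical end dates (overlapping supplies are not stacked
#' end-to-end). The chain stops at the first dispensing outside the allowed
#' gap.
#'
#' @param dispense_date,units_dispensed,daily_number Parallel vectors for the
#'   patient's ACEI dispensings (any order; sorted internally).
#' @param gap_days Maximum allowed days between the theoretical end of
#'   supply and the next dispensing (default 90; six-month variant 180).
#' @return List with `start_date`, `episode_end`, `n_prescriptions`.
#' @export
build_treatment_episode <- function(dispense_date, units_dispensed,
                                    daily_number, gap_days = 90L) {
  if (length(dispense_date) == 0L) {
    stop("no dispensings supplied", call. = FALSE)
  }
  dispense_date <- as_date(dispense_date, "dispense_date")
  ord <- order(dispense_date)
  d <- dispense_date[ord]
  ends <- prescription_end(d, units_dispensed[ord], daily_number[ord])
  episode_end <- ends[1L]
  n <- 1L
  for (i in seq_along(d)[-1L]) {
    if (as.numeric(d[i] - episode_end) > gap_days) break
    episode_end <- max(episode_end, ends[i])
    n <- n + 1L
  }
  list(start_date = d[1L], episode_end = episode_end, n_prescriptions = n)
}

#' Classify one patient's prescription pattern
#'
#' Applies the pattern definitions to a single patient: if follow-up ends no
#' later than `gap_days` after the theoretical end of the ACEI episode the
#' patient is a continuer, subdivided by the reason follow-up ended.
#' Otherwise the episode end becomes the index (switch/stop) date and the
#' window `(index, index + switch_window_days]` is scanned: any ARB
#' dispensing makes the patient a switcher to ARB; failing that, any other
#' antihypertensive dispensing makes a switcher to another antihypertensive;
#' otherwise the patient stopped. Only dispensings before the exit date
#' count.
#'
#' @param dispensing All dispensing rows for the patient (any drug class).
#' @param followup_row Single follow-up row for the patient.
#' @param gap_days Renewal gap defining discontinuation (default 90).
#' @param switch_window_days Window after the index date scanned for
#'   replacement antihypertensives; defaults to `gap_days`.
#' @param class_map ATC prefix map.
#' @return One-row data.frame: `patient_id`, `category`, `index_date`
#'   (`NA` for continuers), `acei_start_date`, `acei_duration_days`
#'   (`min(episode_end, exit_date) - start`), `n_prescriptions`, `gap_days`,
#'   `switch_window_days`.
#' @export
classify_pattern <- function(dispensing, followup_row, gap_days = 90L,
                             switch_window_days = gap_days,
                             class_map = atc_class_map()) {
  cls <- classify_atc(dispensing$atc_code, class_map)
  classify_pattern_(dispensing$patient_id[1L],
                    as_date(dispensing$dispense_date, "dispense_date"),
                    dispensing$units_dispensed, dispensing$daily_number,
                    cls, followup_row$exit_date, followup_row$exit_reason,
                    gap_days, switch_window_days)
}

# core single-patient classifier working on pre-classified vectors
classify_pattern_ <- function(pid, dates, units, daily, cls,
                              exit_date, exit_reason,
                              gap_days, switch_window_days) {
  is_acei <- !is.na(cls) & cls == "ACEI"
  if (!any(is_acei)) stop("patient ", pid, " has no ACEI dispensing",
                          call. = FALSE)
  ep <- build_treatment_episode(dates[is_acei], units[is_acei],
                                daily[is_acei], gap_days)
  start <- ep$start_date
  epi_end <- ep$episode_end
  if (as.numeric(exit_date - epi_end) <= gap_days) {
    category <- switch(as.character(exit_reason),
                       END_OF_STUDY = "CONT_END_OF_STUDY",
                       MOVED_OUT    = "CONT_OUT_OF_STUDY",
                       DEATH        = "CONT_DEATH",
                       stop("unknown exit_reason: ", exit_reason,
                            call. = FALSE))
    index <- as.Date(NA)
    dur <- as.numeric(min(epi_end, exit_date) - start)
  } else {
    index <- epi_end
    dur <- as.numeric(epi_end - start)
    off <- as.numeric(dates - index)
    in_win <- off > 0 & off <= switch_window_days & dates < exit_date
    w_cls <- cls[in_win]
    category <- if (any(w_cls == "ARB", na.rm = TRUE)) {
      "SWITCH_ARB"
    } else if (any(w_cls %in% c("BETA_BLOCKER", "CCB", "DIURETIC",
                                "OTHER_ANTIHYPERTENSIVE"))) {
      "SWITCH_OTHER"
    } else {
      "STOP"
    }
  }
  data.frame(patient_id = pid, category = category, index_date = index,
             acei_start_date = start, acei_duration_days = dur,
             n_prescriptions = ep$n_prescriptions,
             gap_days = as.integer(gap_days),
             switch_window_days = as.integer(switch_window_days),
             stringsAsFactors = FALSE)
}

#' Classify the prescription pattern of every starter in a cohort
#'
#' @inheritParams classify_pattern
#' @inheritParams identify_starters
#' @param starters Optional data.frame from [identify_starters()]; computed
#'   from the inputs when omitted.
#' @return Data frame with one [classify_pattern()] row per starter.
#' @export
classify_patterns <- function(dispensing, followup, gap_days = 90L,
                              switch_window_days = gap_days,
                              study_start = as.Date("2000-01-01"),
                              lookback_days = 182L,
                              class_map = atc_class_map(),
                              starters = NULL) {
  if (is.null(starters)) {
    starters <- identify_starters(dispensing, followup, study_start,
                                  lookback_days, class_map)
  }
  if (nrow(starters) == 0L) {
    return(data.frame(patient_id = character(0), category = character(0),
                      index_date = as.Date(character(0)),
                      acei_start_date = as.Date(character(0)),
                      acei_duration_days = numeric(0),
                      n_prescriptions = integer(0),
                      gap_days = integer(0), switch_window_days = integer(0)))
  }
  keep <- dispensing$patient_id %in% starters$patient_id
  disp <- dispensing[keep, , drop = FALSE]
  cls <- classify_atc(disp$atc_code, class_map)
  dd <- as.integer(as_date(disp$dispense_date, "dispense_date"))
  ends <- as.integer(prescription_end(disp$dispense_date,
                                      disp$units_dispensed,
                                      disp$daily_number))
  idx <- split(seq_len(nrow(disp)), disp$patient_id)
  fu_at <- match(names(idx), followup$patient_id)
  exit_i <- as.integer(as_date(followup$exit_date, "exit_date"))
  reason <- followup$exit_reason
  cont_map <- c(END_OF_STUDY = "CONT_END_OF_STUDY",
                MOVED_OUT = "CONT_OUT_OF_STUDY", DEATH = "CONT_DEATH")
  other_cls <- c("BETA_BLOCKER", "CCB", "DIURETIC", "OTHER_ANTIHYPERTENSIVE")
  np <- length(idx)
  category <- character(np); index_d <- rep(NA_integer_, np)
  start_d <- integer(np); dur <- numeric(np); nrx <- integer(np)
  for (k in seq_len(np)) {
    i <- idx[[k]]
    i <- i[order(dd[i])]
    ai <- i[!is.na(cls[i]) & cls[i] == "ACEI"]
    if (length(ai) == 0L) {
      stop("patient ", names(idx)[k], " has no ACEI dispensing",
           call. = FALSE)
    }
    d <- dd[ai]; en <- ends[ai]
    epi_end <- en[1L]; n <- 1L
    for (j in seq_along(d)[-1L]) {
      if (d[j] - epi_end > gap_days) break
      if (en[j] > epi_end) epi_end <- en[j]
      n <- n + 1L
    }
    ex <- exit_i[fu_at[k]]
    start_d[k] <- d[1L]; nrx[k] <- n
    if (ex - epi_end <= gap_days) {
      rs <- reason[fu_at[k]]
      if (is.na(cont_map[rs])) stop("unknown exit_reason: ", rs,
                                    call. = FALSE)
      category[k] <- cont_map[[rs]]
      dur[k] <- min(epi_end, ex) - d[1L]
    } else {
      index_d[k] <- epi_end
      dur[k] <- epi_end - d[1L]
      off <- dd[i] - epi_end
      win <- off > 0L & off <= switch_window_days & dd[i] < ex
      wcls <- cls[i][win]
      category[k] <- if (any(wcls == "ARB", na.rm = TRUE)) "SWITCH_ARB"
        else if (any(wcls %in% other_cls)) "SWITCH_OTHER"
        else "STOP"
    }
  }
  data.frame(patient_id = names(idx), category = category,
             index_date = as.Date(index_d, origin = "1970-01-01"),
             acei_start_date = as.Date(start_d, origin = "1970-01-01"),
             acei_duration_days = dur, n_prescriptions = nrx,
             gap_days = as.integer(gap_days),
             switch_window_days = as.integer(switch_window_days),
             stringsAsFactors = FALSE)
}

#' Reclassification between two renewal-gap settings
#'
#' Classifies the cohort at two gap settings and cross-tabulates the
#' categories, reporting how many patients change category and how many move
#' from a test-positive group (stop/switch) at the narrow gap to
#' continuation at the wide gap.
#'
#' @inheritParams classify_patterns
#' @param gap_a,gap_b The two renewal gaps in days, `gap_a < gap_b`
#'   (defaults 90 and 180).
#' @return List with `pairs` (per-patient categories at both gaps),
#'   `transitions` (contingency table), `n_changed`, and
#'   `n_positive_to_continuation`.
#' @export
reclassification_delta <- function(dispensing, followup, gap_a = 90L,
                                   gap_b = 180L,
                                   study_start = as.Date("2000-01-01"),
                                   lookback_days = 182L,
                                   class_map = atc_class_map()) {
  if (!(gap_a < gap_b)) stop("gap_a must be smaller than gap_b",
                             call. = FALSE)
  pa <- classify_patterns(dispensing, followup, gap_days = gap_a,
                          study_start = study_start,
                          lookback_days = lookback_days,
                          class_map = class_map)
  pb <- classify_patterns(dispensing, followup, gap_days = gap_b,
                          study_start = study_start,
                          lookback_days = lookback_days,
                          class_map = class_map)
  m <- merge(pa[, c("patient_id", "category")],
             pb[, c("patient_id", "category")],
             by = "patient_id", suffixes = c("_a", "_b"))
  lev <- pattern_categories()
  tab <- table(factor(m$category_a, lev), factor(m$category_b, lev),
               dnn = c(paste0("gap_", gap_a), paste0("gap_", gap_b)))
  pos_to_cont <- m$category_a %in% test_positive_categories() &
    m$category_b %in% continuation_categories()
  list(pairs = m, transitions = tab,
       n_changed = sum(m$category_a != m$category_b),
       n_positive_to_continuation = sum(pos_to_cont))
}
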