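# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# Day-by-day coverage simulation: mark every supplied day, then walk the
# covered days from the start and stop at the first uncovered stretch
# longer than gap_days. Returns the first uncovered day after the last
# chained supply (the episode end).
oracle_episode_end <- function(dates, units, daily, gap_days) {
  dur <- pmax(1, floor(units / daily + 0.5))
  d <- as.integer(as.Date(dates))
  covered <- sort(unique(unlist(mapply(
    function(s, k) seq.int(s, s + k - 1L), d, dur, SIMPLIFY = FALSE))))
  first <- min(d)
  covered <- covered[covered >= first]
  last <- covered[1L]
  for (x in covered[-1L]) {
    if (x - last - 1L > gap_days) break
    last <- x
  }
  as.Date(last + 1L, origin = "1970-01-01")
}

# prefix lookup written independently of classify_atc
oracle_drug_class <- function(atc) {
  p4 <- substr(atc, 1L, 4L)
  p3 <- substr(atc, 1L, 3L)
  ifelse(p4 %in% c("C09A", "C09B"), "ACEI",
  ifelse(p4 %in% c("C09C", "C09D"), "ARB",
  ifelse(p3 == "C07", "BETA_BLOCKER",
  ifelse(p3 == "C08", "CCB",
  ifelse(p3 == "C03", "DIURETIC",
  ifelse(p3 == "C02", "OTHER_ANTIHYPERTENSIVE", NA_character_))))))
}

# Full day-coverage classifier for one patient
oracle_classify <- function(disp, fu_row, gap_days,
                            switch_window_days = gap_days) {
  cls <- oracle_drug_class(disp$atc_code)
  acei <- !is.na(cls) & cls == "ACEI"
  epi_end <- oracle_episode_end(disp$dispense_date[acei],
                                disp$units_dispensed[acei],
                                disp$daily_number[acei], gap_days)
  start <- min(disp$dispense_date[acei])
  exit <- fu_row$exit_date
  if (as.numeric(exit - epi_end) <= gap_days) {
    cat <- c(END_OF_STUDY = "CONT_END_OF_STUDY",
             MOVED_OUT = "CONT_OUT_OF_STUDY",
             DEATH = "CONT_DEATH")[[fu_row$exit_reason]]
    return(list(category = cat, index_date = as.Date(NA)))
  }
  off <- as.numeric(disp$dispense_date - epi_end)
  win <- off > 0 & off <= switch_window_days & disp$dispense_date < exit
  wc <- cls[win]
  cat <- if (any(wc == "ARB", na.rm = TRUE)) "SWITCH_ARB"
    else if (any(wc %in% c("BETA_BLOCKER", "CCB", "DIURETIC",
                           "OTHER_ANTIHYPERTENSIVE"))) "SWITCH_OTHER"
    else "STOP"
  list(category = cat, index_date = epi_end)
}

# Wilson interval by numerically inverting the score equation
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm((1 + conf) / 2)
  p_hat <- x / n
  f <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  lo <- if (x == 0) 0 else
    uniroot(f, c(1e-12, min(p_hat, 1 - 1e-9)), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    uniroot(f, c(max(p_hat, 1e-9), 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# Random messy single-patient dispensing history plus follow-up row,
# stressing overlap, long gaps, fractional daily numbers and concurrent
# non-ACEI drugs.
random_patient <- function(id) {
  n_acei <- sample(1:6, 1L)
  start <- as.Date("2000-01-01") + sample(0:3000, 1L)
  gaps <- sample(0:150, n_acei - 1L, replace = TRUE)
  dates <- start + cumsum(c(0L, gaps))
  units <- sample(c(10, 30, 45, 60, 90), n_acei, replace = TRUE)
  daily <- sample(c(0.5, 1, 2), n_acei, replace = TRUE)
  disp <- data.frame(patient_id = id,
                     atc_code = sample(c("C09AA02", "C09BA05"), n_acei,
                                       replace = TRUE),
                     dispense_date = dates, units_dispensed = units,
                     daily_number = daily, stringsAsFactors = FALSE)
  n_other <- sample(0:3, 1L)
  if (n_other > 0L) {
    disp <- rbind(disp, data.frame(
      patient_id = id,
      atc_code = sample(c("C09CA01", "C07AB02", "C08CA01", "C03AA03",
                          "C02AC01", "C10AA01"), n_other, replace = TRUE),
      dispense_date = max(dates) + sample(-30:250, n_other, replace = TRUE),
      units_dispensed = 30, daily_number = 1, stringsAsFactors = FALSE))
  }
  exit <- max(disp$dispense_date) + sample(30:600, 1L)
  fu <- data.frame(patient_id = id, entry_date = start - sample(182:2000, 1L),
                   exit_date = exit,
                   exit_reason = sample(c("END_OF_STUDY", "MOVED_OUT",
                                          "DEATH"), 1L),
                   stringsAsFactors = FALSE)
  disp <- disp[disp$dispense_date < exit & disp$dispense_date >= fu$entry_date, ]
  list(dispensing = disp, followup = fu)
}

# Assemble a multi-patient random cohort for the oracle-equivalence checks
random_cohort <- function(n, seed) {
  set.seed(seed)
  ps <- lapply(seq_len(n), function(i) random_patient(sprintf("R%04d", i)))
  list(dispensing = do.call(rbind, lapply(ps, `[[`, "dispensing")),
       followup = do.call(rbind, lapply(ps, `[[`, "followup")))
}
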