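#' Parameters for the synthetic ACEI cohort generator
#'
#' Returns a validated parameter list describing the generative model behind
#' [generate_cohort()]. Defaults emulate a Dutch population-based dispensing
#' cohort of ACEI starters followed 2000-2011: 30/90-day supplies dominated
#' by 90-day refills, short refill delays with an occasional long
#' interruption, a latent ADR process driving switching and stopping,
#' incomplete GP recording (definite note / probable phrasing / nothing),
#' background respiratory-type events unrelated to the drug, and censoring
#' by death or moving out of the catchment area.
#'
#' @param n_patients Cohort size (default 1132).
#' @param study_start,study_end Study window (defaults 2000-01-01 and
#'   2011-01-01).
#' @param entry_earliest Earliest database entry date (default 1991-01-01).
#' @param lookback_days Covered ACEI-free history guaranteed before the
#'   first dispensing (default 182).
#' @param presc_lengths,presc_length_probs Supply durations in days and
#'   their mixing probabilities (default 30/90 days at 0.3/0.7).
#' @param daily_number Prescribed units per day (default 1).
#' @param refill_delay_max On-treatment refills occur 0 to this many days
#'   after the theoretical end of supply (default 10).
#' @param p_adr Probability a patient develops an ACEI-induced ADR while on
#'   treatment (default 0.30).
#' @param adr_time_mean Mean of the exponential onset time of the ADR, in
#'   days from ACEI start (default 270; both early and late ADRs occur).
#' @param action_given_adr Named probabilities over
#'   `switch_arb`, `switch_other`, `stop`, `continue` (tolerated ADR).
#' @param p_nonadr_discont Probability a patient without an ADR
#'   discontinues for another reason (no need, not effective; default 0.38).
#' @param nonadr_time_mean Mean exponential latency of non-ADR
#'   discontinuation, days from start (default 270, matching
#'   `adr_time_mean` so censoring thins both causes equally).
#' @param action_given_nonadr Named probabilities over `switch_arb`,
#'   `switch_other`, `stop` for non-ADR discontinuers.
#' @param p_interruption Probability a committed continuer has one long
#'   refill interruption (default 0.12).
#' @param interruption_range Interruption length, uniform over this range in
#'   days (default 91-270, so the 90- vs 180-day gap settings disagree on
#'   part of these patients).
#' @param recording `c(definite=, probable=)`: probability an ADR that ended
#'   treatment is recorded as a definite ADR; else probability of probable
#'   phrasing; otherwise nothing is recorded.
#' @param recording_tolerated Same two probabilities for ADRs the patient
#'   tolerated while continuing (lower: no discontinuation prompts a note).
#' @param p_reason_recorded Probability a non-ADR discontinuation reason is
#'   recorded as a definite non-ADR note (default 0.35).
#' @param adr_terms Named probabilities of the ADR term attached to
#'   definite/probable ADR events (cough dominant, angioedema rare).
#' @param background_rates `c(probable=, non_probable=)`: daily Poisson
#'   rates of drug-unrelated events with probable-ADR-like phrasing (e.g.
#'   bronchitis) and clearly unrelated health problems.
#' @param censor_hazards `c(death=, moved=)`: daily exponential hazards of
#'   death and moving, from ACEI start.
#' @param switch_delay_range Days after the index date at which the
#'   replacement antihypertensive is dispensed (uniform; default 7-60,
#'   inside every switch window considered).
#' @param adr_event_offset,reason_event_offset Uniform placement of the
#'   recorded event relative to the index date, in days.
#' @param seed Optional default seed used by [generate_cohort()].
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 1132L,
                          study_start = "2000-01-01",
                          study_end = "2011-01-01",
                          entry_earliest = "1991-01-01",
                          lookback_days = 182L,
                          presc_lengths = c(30L, 90L),
                          presc_length_probs = c(0.3, 0.7),
                          daily_number = 1,
                          refill_delay_max = 10L,
                          p_adr = 0.30,
                          adr_time_mean = 270,
                          action_given_adr = c(switch_arb = 0.42,
                                               switch_other = 0.12,
                                               stop = 0.20,
                                               continue = 0.26),
                          p_nonadr_discont = 0.38,
                          nonadr_time_mean = 270,
                          action_given_nonadr = c(switch_arb = 0.12,
                                                  switch_other = 0.22,
                                                  stop = 0.66),
                          p_interruption = 0.12,
                          interruption_range = c(91L, 270L),
                          recording = c(definite = 0.70, probable = 0.55),
                          recording_tolerated = c(definite = 0.25,
                                                  probable = 0.30),
                          p_reason_recorded = 0.35,
                          adr_terms = c(cough = 0.735, angioedema = 0.03,
                                        dizziness = 0.09, other = 0.145),
                          background_rates = c(probable = 2e-4,
                                               non_probable = 1e-4),
                          censor_hazards = c(death = 8e-5, moved = 1.1e-4),
                          switch_delay_range = c(7L, 60L),
                          adr_event_offset = c(-60L, 30L),
                          reason_event_offset = c(-30L, 14L),
                          seed = NULL) {
  p <- as.list(environment())
  check_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("probabilities in ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  check_prob(p$p_adr, "p_adr"); check_prob(p$p_nonadr_discont,
                                           "p_nonadr_discont")
  check_prob(p$action_given_adr, "action_given_adr")
  check_prob(p$action_given_nonadr, "action_given_nonadr")
  check_prob(p$recording, "recording")
  check_prob(p$recording_tolerated, "recording_tolerated")
  check_prob(p$p_reason_recorded, "p_reason_recorded")
  check_prob(p$p_interruption, "p_interruption")
  check_prob(p$adr_terms, "adr_terms"); check_prob(p$presc_length_probs,
                                                   "presc_length_probs")
  if (abs(sum(p$action_given_adr) - 1) > 1e-8 ||
      abs(sum(p$action_given_nonadr) - 1) > 1e-8 ||
      abs(sum(p$adr_terms) - 1) > 1e-8 ||
      abs(sum(p$presc_length_probs) - 1) > 1e-8) {
    stop("action, term and supply-length probabilities must sum to 1",
         call. = FALSE)
  }
  if (any(p$presc_lengths <= 0) || any(p$background_rates < 0) ||
      any(p$censor_hazards < 0) || p$adr_time_mean <= 0 ||
      p$nonadr_time_mean <= 0) {
    stop("durations, rates and hazards must be non-negative", call. = FALSE)
  }
  if (p$interruption_range[1L] > p$interruption_range[2L]) {
    stop("interruption_range must be increasing", call. = FALSE)
  }
  class(p) <- "cohort_params"
  p
}

# exponential draw that tolerates a zero rate (no event: +Inf)
rexp0 <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Generate a synthetic dispensing cohort with latent ADR ground truth
#'
#' Simulates, per patient: an ACEI start uniform over the study window, a
#' refill chain following the supply-length mixture, censoring by death or
#' moving, a latent ADR (exponential onset) competing with non-ADR
#' discontinuation, the resulting dispensing pattern (replacement ARB/other
#' dispensing, bare stop, or continued refills with an occasional long
#' interruption), and coded GP events generated by the recording model plus
#' background events. Deterministic for a given seed.
#'
#' @param params A [cohort_params()] list.
#' @param seed Integer seed; overrides `params$seed`.
#' @return List with data frames `dispensing`, `followup`, `gp_events`, and
#'   `ground_truth` (latent ADR indicator, intent, onset date, whether the
#'   discontinuation materialised before censoring, and the ADR-linked or
#'   reason-linked recorded code with its event date).
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  with_seed(as.integer(seed), generate_cohort_(params))
}

generate_cohort_ <- function(p) {
  n <- p$n_patients
  d0 <- as.integer(as.Date(p$study_start))
  d1 <- as.integer(as.Date(p$study_end))
  e0 <- as.integer(as.Date(p$entry_earliest))

  start <- d0 + floor(stats::runif(n) * (d1 - d0 - 30L))
  entry <- pmax(e0, start - p$lookback_days -
                  floor(stats::runif(n) * 3000))
  t_death <- ceiling(rexp0(n, p$censor_hazards[["death"]]))
  t_moved <- ceiling(rexp0(n, p$censor_hazards[["moved"]]))
  exit <- pmin(d1, start + pmin(t_death, t_moved))
  exit_reason <- ifelse(start + pmin(t_death, t_moved) >= d1, "END_OF_STUDY",
                        ifelse(t_death <= t_moved, "DEATH", "MOVED_OUT"))

  has_adr <- stats::runif(n) < p$p_adr
  adr_action <- sample(names(p$action_given_adr), n, replace = TRUE,
                       prob = p$action_given_adr)
  nd <- !has_adr & stats::runif(n) < p$p_nonadr_discont
  nd_action <- sample(names(p$action_given_nonadr), n, replace = TRUE,
                      prob = p$action_given_nonadr)
  t_adr <- ceiling(rexp0(n, 1 / p$adr_time_mean))
  t_nd <- ceiling(rexp0(n, 1 / p$nonadr_time_mean))

  intent <- rep("continue", n)            # committed continuer
  stop_offset <- rep(Inf, n)              # treatment time to cover before stopping
  adr_discont <- has_adr & adr_action != "continue"
  intent[adr_discont] <- paste0("adr_", adr_action[adr_discont])
  stop_offset[adr_discont] <- t_adr[adr_discont]
  intent[has_adr & adr_action == "continue"] <- "tolerated_adr"
  intent[nd] <- paste0("nonadr_", nd_action[nd])
  stop_offset[nd] <- t_nd[nd]

  plain <- intent == "continue"
  interrupted <- plain & stats::runif(n) < p$p_interruption
  int_len <- floor(stats::runif(n, p$interruption_range[1L],
                                p$interruption_range[2L] + 1))
  int_frac <- stats::runif(n, 0.1, 0.9)

  other_atc <- c("C07AB02", "C08CA01", "C03AA03", "C02AC01")
  dl <- vector("list", n); ev <- vector("list", n)
  acted <- logical(n); index_day <- rep(NA_real_, n)
  recorded <- rep("NONE", n); adr_day <- rep(NA_real_, n)
  recorded_day <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    s <- start[i]; e <- exit[i]; fup <- e - s
    nmax <- ceiling(fup / min(p$presc_lengths)) + 2L
    lens <- sample(p$presc_lengths, nmax, replace = TRUE,
                   prob = p$presc_length_probs)
    delays <- floor(stats::runif(nmax) * (p$refill_delay_max + 1L))
    so <- stop_offset[i]
    int_at <- if (interrupted[i]) int_frac[i] * fup else Inf
    int_done <- FALSE
    t <- s; cover_end <- s; k <- 0L
    days <- numeric(nmax); plen <- numeric(nmax)
    while (t < e && k < nmax) {
      k <- k + 1L
      days[k] <- t
      plen[k] <- lens[k]
      cover_end <- t + lens[k]
      if (cover_end - s >= so) break
      t <- cover_end + delays[k]
      if (!int_done && cover_end - s >= int_at) {
        t <- t + int_len[i]
        int_done <- TRUE
      }
    }
    index_day[i] <- cover_end
    acted[i] <- is.finite(so) && cover_end - s >= so && cover_end < e

    pid_days <- days[seq_len(k)]
    pid_lens <- plen[seq_len(k)]
    atc <- rep("C09AA02", k)

    # replacement antihypertensive inside the switch window
    if (acted[i] && intent[i] %in% c("adr_switch_arb", "adr_switch_other",
                                     "nonadr_switch_arb",
                                     "nonadr_switch_other")) {
      sw_day <- cover_end + floor(stats::runif(1, p$switch_delay_range[1L],
                                               p$switch_delay_range[2L] + 1))
      if (sw_day < e) {
        pid_days <- c(pid_days, sw_day)
        pid_lens <- c(pid_lens, 90)
        atc <- c(atc, if (endsWith(intent[i], "switch_arb")) "C09CA01"
                 else sample(other_atc, 1L))
      }
    }
    dl[[i]] <- list(days = pid_days, lens = pid_lens, atc = atc)

    # ADR-linked / reason-linked GP event
    ecode <- character(0); eday <- numeric(0); eterm <- character(0)
    if (acted[i] && startsWith(intent[i], "adr_")) {
      u <- stats::runif(2)
      code <- if (u[1L] < p$recording[["definite"]]) "DEFINITE_ADR"
        else if (u[2L] < p$recording[["probable"]]) "PROBABLE_ADR" else NA
      if (!is.na(code)) {
        day <- cover_end + floor(stats::runif(1, p$adr_event_offset[1L],
                                              p$adr_event_offset[2L] + 1))
        ecode <- code
        eday <- min(max(day, entry[i]), e)
        eterm <- sample(names(p$adr_terms), 1L, prob = p$adr_terms)
        recorded[i] <- code
        recorded_day[i] <- eday
      }
      adr_day[i] <- s + stop_offset[i]
    } else if (intent[i] == "tolerated_adr") {
      adr_day[i] <- s + min(t_adr[i], max(1, fup - 30))
      u <- stats::runif(2)
      code <- if (u[1L] < p$recording_tolerated[["definite"]]) "DEFINITE_ADR"
        else if (u[2L] < p$recording_tolerated[["probable"]]) "PROBABLE_ADR"
        else NA
      if (!is.na(code)) {
        ecode <- code
        eday <- adr_day[i]
        eterm <- sample(names(p$adr_terms), 1L, prob = p$adr_terms)
        recorded[i] <- code
        recorded_day[i] <- eday
      }
    } else if (acted[i] && startsWith(intent[i], "nonadr_")) {
      if (stats::runif(1) < p$p_reason_recorded) {
        day <- cover_end + floor(stats::runif(1, p$reason_event_offset[1L],
                                              p$reason_event_offset[2L] + 1))
        ecode <- "DEFINITE_NON_ADR"
        eday <- min(max(day, entry[i]), e)
        eterm <- NA_character_
        recorded[i] <- "DEFINITE_NON_ADR"
        recorded_day[i] <- eday
      }
    }
    # background events over the whole follow-up
    span <- e - entry[i]
    nbp <- stats::rpois(1, p$background_rates[["probable"]] * span)
    nbn <- stats::rpois(1, p$background_rates[["non_probable"]] * span)
    if (nbp > 0L) {
      ecode <- c(ecode, rep("PROBABLE_ADR", nbp))
      eday <- c(eday, entry[i] + floor(stats::runif(nbp) * (span + 1)))
      eterm <- c(eterm, sample(c("bronchitis", "common_cold",
                                 "infectious_cough", "copd", "dizziness",
                                 "dyspnea"), nbp, replace = TRUE))
    }
    if (nbn > 0L) {
      ecode <- c(ecode, rep("NON_PROBABLE_HP", nbn))
      eday <- c(eday, entry[i] + floor(stats::runif(nbn) * (span + 1)))
      eterm <- c(eterm, rep(NA_character_, nbn))
    }
    ev[[i]] <- list(code = ecode, day = eday, term = eterm)
  }

  ids <- sprintf("P%05d", seq_len(n))
  nrx <- vapply(dl, function(x) length(x$days), integer(1))
  dispensing <- data.frame(
    patient_id = rep(ids, nrx),
    atc_code = unlist(lapply(dl, `[[`, "atc"), use.names = FALSE),
    dispense_date = as.Date(unlist(lapply(dl, `[[`, "days"),
                                   use.names = FALSE), origin = "1970-01-01"),
    units_dispensed = unlist(lapply(dl, `[[`, "lens"), use.names = FALSE) *
      p$daily_number,
    daily_number = p$daily_number,
    stringsAsFactors = FALSE)
  followup <- data.frame(
    patient_id = ids,
    entry_date = as.Date(entry, origin = "1970-01-01"),
    exit_date = as.Date(exit, origin = "1970-01-01"),
    exit_reason = exit_reason,
    stringsAsFactors = FALSE)
  nev <- vapply(ev, function(x) length(x$code), integer(1))
  gp_events <- data.frame(
    patient_id = rep(ids, nev),
    event_date = as.Date(unlist(lapply(ev, `[[`, "day"),
                                use.names = FALSE), origin = "1970-01-01"),
    adjudication_code = unlist(lapply(ev, `[[`, "code"), use.names = FALSE),
    adr_term = unlist(lapply(ev, `[[`, "term"), use.names = FALSE),
    stringsAsFactors = FALSE)
  ground_truth <- data.frame(
    patient_id = ids,
    has_adr = has_adr,
    intent = intent,
    acted = acted,
    adr_date = as.Date(adr_day, origin = "1970-01-01"),
    index_date = as.Date(index_day, origin = "1970-01-01"),
    recorded_code = recorded,
    recorded_date = as.Date(recorded_day, origin = "1970-01-01"),
    interrupted = interrupted,
    interruption_days = ifelse(interrupted, int_len, NA_integer_),
    stringsAsFactors = FALSE)
  list(dispensing = dispensing, followup = followup, gp_events = gp_events,
       ground_truth = ground_truth)
}
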