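#' Pipeline configuration
#'
#' Collects every setting of the validation pipeline with defaults matching
#' the published design: 90/180-day renewal gaps, switch window tied to the
#' gap, adjudication window 180 days before to 90 days after the index
#' date, 182-day (six-month) ACEI-free lookback, Wilson 95% intervals.
#'
#' @param dispensing,followup,gp_events Data frames, or paths to CSV files
#'   in the documented dialects.
#' @param study_start Inclusion window start (default 2000-01-01).
#' @param lookback_days Required ACEI-free history (default 182).
#' @param gap_days Integer vector of renewal gaps to analyse
#'   (default `c(90, 180)`).
#' @param switch_window_days `NULL` to tie the post-index switch scan to
#'   each gap (default), or a fixed number of days.
#' @param before_days,after_days Adjudication window around the index date.
#' @param conf_level,ci_method Confidence interval settings, see
#'   [binom_interval()].
#' @param seed Seed for the matched-control sampling.
#' @param out_dir Optional directory for the report CSVs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dispensing, followup, gp_events,
                            study_start = as.Date("2000-01-01"),
                            lookback_days = 182L,
                            gap_days = c(90L, 180L),
                            switch_window_days = NULL,
                            before_days = 180L, after_days = 90L,
                            conf_level = 0.95, ci_method = "wilson",
                            seed = 1L, out_dir = NULL) {
  cfg <- list(
    dispensing = if (is.character(dispensing)) read_dispensing(dispensing)
      else dispensing,
    followup = if (is.character(followup)) read_followup(followup)
      else followup,
    gp_events = if (is.character(gp_events)) read_gp_events(gp_events)
      else gp_events,
    study_start = as_date(study_start, "study_start"),
    lookback_days = lookback_days,
    gap_days = as.integer(gap_days),
    switch_window_days = switch_window_days,
    before_days = before_days, after_days = after_days,
    conf_level = conf_level,
    ci_method = match.arg(ci_method,
                          c("wilson", "clopper-pearson", "wald")),
    seed = as.integer(seed), out_dir = out_dir)
  if (any(cfg$gap_days <= 0)) stop("gap_days must be positive",
                                   call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

estimate_row <- function(est, measure, group, level, gap,
                         term = NA_character_) {
  data.frame(measure = measure, group = group, level = level, adr_term = term,
             numerator = est$numerator, denominator = est$denominator,
             estimate_pct = 100 * est$estimate,
             ci_low_pct = 100 * est$ci_low, ci_high_pct = 100 * est$ci_high,
             gap_days = gap, stringsAsFactors = FALSE)
}

#' Accuracy metrics from a validation counts table (counts mode)
#'
#' Computes every PPV (all test-positive groups and margins at the three
#' ascertainment levels, plus the cough-restricted definite PPV) and every
#' NPV (all continuation subgroups and margins at the two defined levels)
#' from a prefilled counts table. This is the entry point for reproducing
#' published tables when only aggregate counts are available.
#'
#' @param counts A [validation_counts()] object, e.g. [table2_fixture()].
#' @param conf_level,ci_method Interval settings.
#' @param gap_days Value recorded in the `gap_days` report column
#'   (informational; default `NA`).
#' @return Data frame with one row per estimate: measure, group, level,
#'   numerator, denominator, estimate and CI bounds in percent.
#' @export
run_counts_pipeline <- function(counts, conf_level = 0.95,
                                ci_method = "wilson", gap_days = NA) {
  pos_groups <- c("SWITCH_ARB", "SWITCH_OTHER", "STOP", "SWITCHERS_TOTAL",
                  "TOTAL_DISCONTINUATION")
  neg_groups <- c("CONT_END_OF_STUDY", "CONT_OUT_OF_STUDY", "CONT_DEATH",
                  "CONTINUATION_MINUS_DEATH", "CONTINUATION_TOTAL")
  rows <- list()
  for (g in pos_groups) {
    for (lv in ascertainment_levels()) {
      rows[[length(rows) + 1L]] <-
        estimate_row(ppv(counts, g, lv, conf_level = conf_level,
                         ci_method = ci_method), "PPV", g, lv, gap_days)
    }
    if (!is.null(counts$definite_terms)) {
      rows[[length(rows) + 1L]] <-
        estimate_row(ppv(counts, g, "DEFINITE", term_filter = "cough",
                         conf_level = conf_level, ci_method = ci_method),
                     "PPV", g, "DEFINITE", gap_days, term = "cough")
    }
  }
  for (g in neg_groups) {
    for (lv in c("AT_LEAST_POSSIBLE", "AT_LEAST_PROBABLE")) {
      rows[[length(rows) + 1L]] <-
        estimate_row(npv(counts, g, lv, conf_level = conf_level,
                         ci_method = ci_method), "NPV", g, lv, gap_days)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

duration_summary <- function(patterns) {
  cats <- c(pattern_categories(), "TOTAL")
  rows <- lapply(cats, function(cat) {
    d <- if (cat == "TOTAL") patterns$acei_duration_days
      else patterns$acei_duration_days[patterns$category == cat]
    data.frame(category = cat, n = length(d),
               median_days = if (length(d)) stats::median(d) else NA_real_,
               mean_days = if (length(d)) mean(d) else NA_real_,
               sd_days = if (length(d) > 1L) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

matched_accuracy <- function(patterns, events, group, seed,
                             conf_level, ci_method) {
  cases <- patterns[patterns$category %in% group_members(group), ,
                    drop = FALSE]
  continuers <- patterns[patterns$category %in% continuation_categories(), ,
                         drop = FALSE]
  if (nrow(cases) == 0L || nrow(continuers) == 0L) return(NULL)
  mm <- match_controls(cases, continuers, seed = seed)
  if (nrow(mm$pairs) == 0L) return(NULL)
  case_adj <- adjudicate_cohort(
    cases[match(mm$pairs$case_id, cases$patient_id), , drop = FALSE],
    events)
  ctrl <- continuers[match(mm$pairs$control_id, continuers$patient_id), ,
                     drop = FALSE]
  ctrl_pat <- ctrl
  ctrl_pat$acei_duration_days <- mm$pairs$evaluation_duration_days
  ctrl_adj <- adjudicate_cohort(ctrl_pat, events)
  ss <- sensitivity_specificity(case_adj$patient_class,
                                ctrl_adj$patient_class,
                                conf_level, ci_method)
  list(result = ss, pairs = mm$pairs, unmatched = mm$unmatched,
       case_classes = case_adj$patient_class,
       control_classes = ctrl_adj$patient_class)
}

#' Run the full patient-level validation pipeline
#'
#' For each configured renewal gap: identifies starters, classifies
#' prescription patterns, adjudicates medical-record events (test-positive
#' patients around the index date, continuers over their whole episode),
#' tabulates the counts, and computes all predictive values plus
#' duration-matched sensitivity and specificity for each test-positive
#' group. When two or more gaps are configured the reclassification between
#' the first two is reported. With `out_dir` set, writes `counts.csv`,
#' `metrics.csv`, `durations.csv`, `reclassification.csv` and a run log;
#' partial outputs are removed if any stage fails.
#'
#' @param config A [pipeline_config()].
#' @return List with per-gap results (`patterns`, `adjudications`, `counts`,
#'   `metrics`, `durations`, `matched`), the combined `metrics` table, and
#'   `reclassification` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_cohort_integrity(config$dispensing, config$followup,
                         config$gp_events)
  starters <- identify_starters(config$dispensing, config$followup,
                                config$study_start, config$lookback_days)
  if (nrow(starters) == 0L) {
    res <- list(starters = starters, by_gap = list(), metrics = NULL,
                reclassification = NULL, note = "no starters")
    return(res)
  }
  by_gap <- list()
  metrics <- list()
  for (gi in seq_along(config$gap_days)) {
    gap <- config$gap_days[gi]
    sw <- if (is.null(config$switch_window_days)) gap
      else config$switch_window_days
    patterns <- classify_patterns(config$dispensing, config$followup,
                                  gap_days = gap, switch_window_days = sw,
                                  study_start = config$study_start,
                                  lookback_days = config$lookback_days,
                                  starters = starters)
    adj <- adjudicate_cohort(patterns, config$gp_events,
                             config$before_days, config$after_days)
    counts <- tabulate_validation(patterns, adj)
    met <- run_counts_pipeline(counts, config$conf_level, config$ci_method,
                               gap_days = gap)
    matched <- list()
    for (g in c("SWITCH_ARB", "SWITCH_OTHER", "STOP", "SWITCHERS_TOTAL")) {
      ma <- matched_accuracy(patterns, config$gp_events, g,
                             seed = config$seed + 13L * gi +
                               match(g, c("SWITCH_ARB", "SWITCH_OTHER",
                                          "STOP", "SWITCHERS_TOTAL")),
                             config$conf_level, config$ci_method)
      if (!is.null(ma)) {
        matched[[g]] <- ma
        met <- rbind(met,
                     estimate_row(ma$result$sensitivity, "sensitivity", g,
                                  "DEFINITE", gap),
                     estimate_row(ma$result$specificity, "specificity", g,
                                  "DEFINITE", gap))
      }
    }
    by_gap[[as.character(gap)]] <-
      list(gap_days = gap, patterns = patterns, adjudications = adj,
           counts = counts, metrics = met,
           durations = duration_summary(patterns), matched = matched)
    metrics[[gi]] <- met
  }
  recl <- if (length(config$gap_days) >= 2L) {
    reclassification_delta(config$dispensing, config$followup,
                           config$gap_days[1L], config$gap_days[2L],
                           study_start = config$study_start,
                           lookback_days = config$lookback_days)
  } else NULL
  res <- list(starters = starters, by_gap = by_gap,
              metrics = do.call(rbind, metrics), reclassification = recl)
  if (!is.null(config$out_dir)) write_reports(res, config)
  res
}

round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up to one decimal

write_reports <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("counts.csv", "metrics.csv", "durations.csv",
                       "reclassification.csv", "run_log.txt"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))
  counts <- do.call(rbind, lapply(res$by_gap, function(bg) {
    cbind(bg$counts$table, gap_days = bg$gap_days)
  }))
  utils::write.csv(counts, paths[1L], row.names = FALSE)
  met <- res$metrics
  for (col in c("estimate_pct", "ci_low_pct", "ci_high_pct")) {
    met[[col]] <- round1(met[[col]])
  }
  utils::write.csv(met, paths[2L], row.names = FALSE, na = "")
  dur <- do.call(rbind, lapply(res$by_gap, function(bg) {
    cbind(bg$durations, gap_days = bg$gap_days)
  }))
  utils::write.csv(dur, paths[3L], row.names = FALSE)
  if (!is.null(res$reclassification)) {
    utils::write.csv(as.data.frame(res$reclassification$transitions),
                     paths[4L], row.names = FALSE)
  }
  writeLines(c(
    paste0("adrproxy version: ",
           as.character(utils::packageVersion("adrproxy"))),
    paste0("run date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", config$seed),
    paste0("study_start: ", config$study_start),
    paste0("lookback_days: ", config$lookback_days),
    paste0("gap_days: ", paste(config$gap_days, collapse = ", ")),
    paste0("switch_window_days: ",
           if (is.null(config$switch_window_days)) "tied to gap"
           else config$switch_window_days),
    paste0("adjudication window: -", config$before_days, "/+",
           config$after_days, " days"),
    paste0("ci: ", config$ci_method, " ", config$conf_level)),
    paths[5L])
  ok <- TRUE
  invisible(paths)
}
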