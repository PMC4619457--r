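d <- function(x) as.Date(x)

test_that("theoretical end date divides units by the daily number", {
  expect_equal(prescription_end(d("2000-01-01"), 90, 1), d("2000-03-31"))
  expect_equal(prescription_end(d("2000-01-01"), 30, 2), d("2000-01-16"))
  expect_equal(prescription_end(d("2000-01-01"), 1, 1), d("2000-01-02"))
  # half-up rounding of fractional days, and the one-day floor
  expect_equal(prescription_end(d("2000-01-01"), 45, 2), d("2000-01-24"))
  expect_equal(prescription_end(d("2000-01-01"), 1, 4), d("2000-01-02"))
  expect_error(prescription_end(d("2000-01-01"), 0, 1), "positive")
  expect_error(prescription_end(d("2000-01-01"), 30, -1), "positive")
})

make_disp <- function(id, dates, atc = "C09AA02", units = 90, daily = 1) {
  data.frame(patient_id = id, atc_code = atc, dispense_date = as.Date(dates),
             units_dispensed = units, daily_number = daily,
             stringsAsFactors = FALSE)
}
make_fu <- function(id, entry, exit, reason = "END_OF_STUDY") {
  data.frame(patient_id = id, entry_date = as.Date(entry),
             exit_date = as.Date(exit), exit_reason = reason,
             stringsAsFactors = FALSE)
}

test_that("starter inclusion needs covered, ACEI-free six-month history", {
  disp <- rbind(
    make_disp("long_history", "2000-03-01"),
    make_disp("prior_use", c("1999-12-01", "2000-02-01")),
    make_disp("short_history", "2000-03-01"))
  fu <- rbind(make_fu("long_history", "1991-01-01", "2011-01-01"),
              make_fu("prior_use", "1991-01-01", "2011-01-01"),
              make_fu("short_history", "2000-01-15", "2011-01-01"))
  st <- identify_starters(disp, fu)
  expect_identical(st$patient_id, "long_history")
  expect_equal(st$first_acei_date, d("2000-03-01"))
})

test_that("starters before the study window or without follow-up fail", {
  disp <- make_disp("early", "1999-06-01")
  fu <- make_fu("early", "1991-01-01", "2011-01-01")
  expect_equal(nrow(identify_starters(disp, fu)), 0L)
  expect_error(identify_starters(make_disp("ghost", "2001-01-01"), fu),
               "without follow-up")
})

test_that("episode chaining respects the renewal gap and stockpiling", {
  # 90-day supply ends 2001-01-01; renewal 73 days later chains
  ep <- build_treatment_episode(d(c("2000-10-03", "2001-03-15")),
                                c(90, 90), c(1, 1), gap_days = 90)
  expect_equal(ep$episode_end, d("2001-06-13"))
  expect_equal(ep$n_prescriptions, 2L)
  # renewal 120 days after the end does not chain at a 90-day gap
  ep <- build_treatment_episode(d(c("2000-10-03", "2001-05-01")),
                                c(90, 90), c(1, 1), gap_days = 90)
  expect_equal(ep$episode_end, d("2001-01-01"))
  expect_equal(ep$n_prescriptions, 1L)
  # single prescription
  ep <- build_treatment_episode(d("2000-01-01"), 30, 1, gap_days = 90)
  expect_equal(ep$episode_end, d("2000-01-31"))
  # overlapping early refill: episode end is the running maximum, not the
  # sum of supplies
  ep <- build_treatment_episode(d(c("2000-01-01", "2000-01-10")),
                                c(90, 30), c(1, 1), gap_days = 90)
  expect_equal(ep$episode_end, d("2000-03-31"))
  # unsorted input is sorted internally
  ep2 <- build_treatment_episode(d(c("2000-01-10", "2000-01-01")),
                                 c(30, 90), c(1, 1), gap_days = 90)
  expect_equal(ep2$episode_end, ep$episode_end)
  expect_error(build_treatment_episode(as.Date(character(0)), numeric(0),
                                       numeric(0)), "no dispensings")
})

test_that("switch and stop classification scans the post-index window", {
  fu <- make_fu("p", "1995-01-01", "2011-01-01")
  # ACEI ends 2005-06-01; ARB six weeks later -> switch to ARB
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-07-15", atc = "C09CA01", units = 30))
  res <- classify_pattern(disp, fu, gap_days = 90)
  expect_identical(res$category, "SWITCH_ARB")
  expect_equal(res$index_date, d("2005-06-01"))
  expect_equal(res$acei_start_date, d("2005-03-03"))
  expect_equal(res$acei_duration_days, 90)
  # beta blocker and no ARB -> switch to other antihypertensive
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-06-20", atc = "C07AB02", units = 30))
  expect_identical(classify_pattern(disp, fu, gap_days = 90)$category,
                   "SWITCH_OTHER")
  # ARB outranks another antihypertensive in the same window
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-06-10", atc = "C07AB02", units = 30),
                make_disp("p", "2005-08-01", atc = "C09CA01", units = 30))
  expect_identical(classify_pattern(disp, fu, gap_days = 90)$category,
                   "SWITCH_ARB")
  # nothing dispensed in the window -> stop
  disp <- make_disp("p", "2005-03-03")
  res <- classify_pattern(disp, fu, gap_days = 90)
  expect_identical(res$category, "STOP")
  expect_equal(res$index_date, d("2005-06-01"))
  # a dispensing exactly at index + window still counts (closed end)
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-08-30", atc = "C09CA01", units = 30))
  expect_identical(classify_pattern(disp, fu, gap_days = 90)$category,
                   "SWITCH_ARB")
  # one day past the window does not
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-08-31", atc = "C09CA01", units = 30))
  expect_identical(classify_pattern(disp, fu, gap_days = 90)$category,
                   "STOP")
})

test_that("continuation is subdivided by the reason follow-up ended", {
  # supply covers to 2010-12-20, study ends 12 days later: continuer
  disp <- make_disp("p", "2010-09-21")
  res <- classify_pattern(disp, make_fu("p", "1995-01-01", "2011-01-01"),
                          gap_days = 90)
  expect_identical(res$category, "CONT_END_OF_STUDY")
  expect_true(is.na(res$index_date))
  # duration is censored at exit when the supply outlives follow-up
  res <- classify_pattern(make_disp("p", "2005-01-01"),
                          make_fu("p", "1995-01-01", "2005-02-01", "DEATH"),
                          gap_days = 90)
  expect_identical(res$category, "CONT_DEATH")
  expect_equal(res$acei_duration_days, 31)
  res <- classify_pattern(make_disp("p", "2005-01-01"),
                          make_fu("p", "1995-01-01", "2005-05-01",
                                  "MOVED_OUT"), gap_days = 90)
  expect_identical(res$category, "CONT_OUT_OF_STUDY")
})

test_that("exit inside the switch window censors the scan", {
  # ACEI supply ends 2005-06-01; with a 90-day gap but a 180-day switch
  # window, an ARB dispensed on the day the patient moved out is ignored
  disp <- rbind(make_disp("p", "2005-03-03"),
                make_disp("p", "2005-09-29", atc = "C09CA01", units = 30))
  fu <- make_fu("p", "1995-01-01", "2005-09-29", "MOVED_OUT")
  expect_identical(
    classify_pattern(disp, fu, gap_days = 90,
                     switch_window_days = 180)$category, "STOP")
  # with later exit the same dispensing counts
  fu$exit_date <- as.Date("2005-12-01")
  expect_identical(
    classify_pattern(disp, fu, gap_days = 90,
                     switch_window_days = 180)$category, "SWITCH_ARB")
})

test_that("a mid-treatment gap of 122 days reclassifies between 90 and 180", {
  # supply ends 2005-04-01, renewal 122 days later, follow-up ends soon
  # after the second supply runs out
  disp <- rbind(make_disp("p", "2005-01-01"),
                make_disp("p", "2005-08-01"))
  fu <- make_fu("p", "1995-01-01", "2005-12-01", "MOVED_OUT")
  expect_identical(classify_pattern(disp, fu, gap_days = 90)$category,
                   "STOP")
  expect_identical(classify_pattern(disp, fu, gap_days = 180)$category,
                   "CONT_OUT_OF_STUDY")
  rd <- reclassification_delta(disp, fu, 90, 180)
  expect_equal(rd$n_changed, 1L)
  expect_equal(rd$n_positive_to_continuation, 1L)
  expect_error(reclassification_delta(disp, fu, 180, 90), "smaller")
})

test_that("classifier equals the day-coverage oracle on random patients", {
  co <- random_cohort(300, seed = 421)
  for (gap in c(60L, 90L, 180L)) {
    pat <- classify_patterns(co$dispensing, co$followup, gap_days = gap)
    expect_equal(nrow(pat), nrow(co$followup))
    for (k in seq_len(nrow(pat))) {
      id <- pat$patient_id[k]
      orc <- oracle_classify(
        co$dispensing[co$dispensing$patient_id == id, , drop = FALSE],
        co$followup[co$followup$patient_id == id, , drop = FALSE], gap)
      expect_identical(pat$category[k], orc$category)
      expect_equal(pat$index_date[k], orc$index_date)
    }
  }
})

test_that("categories are exhaustive and continuation is gap-monotone", {
  co <- random_cohort(400, seed = 99)
  p90 <- classify_patterns(co$dispensing, co$followup, gap_days = 90)
  p180 <- classify_patterns(co$dispensing, co$followup, gap_days = 180)
  expect_true(all(p90$category %in% pattern_categories()))
  expect_equal(sum(table(p90$category)), nrow(co$followup))
  cont90 <- p90$patient_id[p90$category %in% continuation_categories()]
  cont180 <- p180$patient_id[p180$category %in% continuation_categories()]
  expect_true(all(cont90 %in% cont180))
  # index dates of test positives sit between first dispensing and exit
  pos <- p90[p90$category %in% test_positive_categories(), ]
  at <- match(pos$patient_id, co$followup$patient_id)
  expect_true(all(pos$index_date <= co$followup$exit_date[at]))
  expect_true(all(pos$index_date >= pos$acei_start_date))
})
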