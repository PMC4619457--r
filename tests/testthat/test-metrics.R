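test_that("tabulation produces a consistent contingency table", {
  patterns <- data.frame(
    patient_id = c("a", "b", "c"),
    category = c("SWITCH_ARB", "STOP", "CONT_END_OF_STUDY"),
    stringsAsFactors = FALSE)
  adj <- data.frame(
    patient_id = c("a", "b", "c"),
    patient_class = c("DEFINITE_ADR", "NOTHING_MENTIONED", "PROBABLE_ADR"),
    adr_term = c("cough", NA, "bronchitis"),
    stringsAsFactors = FALSE)
  cts <- tabulate_validation(patterns, adj)
  tab <- cts$table
  expect_equal(sum(tab$n), 3L)
  expect_equal(tab$definite_adr[tab$category == "SWITCH_ARB"], 1L)
  expect_equal(tab$nothing_mentioned[tab$category == "STOP"], 1L)
  expect_equal(tab$probable_adr[tab$category == "CONT_END_OF_STUDY"], 1L)
  expect_equal(cts$definite_terms$count, 1L)
  # empty cohort -> all-zero table
  cts0 <- tabulate_validation(patterns[0, ], adj[0, ])
  expect_equal(sum(cts0$table$n), 0L)
  # mismatched patients are a data-integrity error
  expect_error(tabulate_validation(patterns, adj[-1, ]), "same patients")
})

test_that("validation_counts rejects inconsistent tables", {
  cts <- table2_fixture()
  bad <- cts$table
  bad$definite_adr[1] <- bad$definite_adr[1] + 1L
  expect_error(validation_counts(bad), "sum to category n")
  expect_error(validation_counts(cts$table[-1, ]), "one row per")
})

test_that("the published fixture has the printed margins", {
  cts <- table2_fixture()
  expect_equal(sum(cts$table$n), 1132L)
  g <- adrproxy:::group_counts(cts, "TOTAL_DISCONTINUATION")
  expect_equal(unname(g[["n"]]), 547L)
  expect_equal(unname(g[["definite_adr"]]), 194L)
  expect_equal(unname(adrproxy:::group_counts(cts,
                                              "SWITCHERS_TOTAL")[["n"]]),
               286L)
  expect_equal(unname(adrproxy:::group_counts(
    cts, "CONTINUATION_TOTAL")[["n"]]), 585L)
  expect_equal(unname(adrproxy:::group_counts(
    cts, "CONTINUATION_MINUS_DEATH")[["n"]]), 466L)
})

test_that("predictive values are the level counts over the group size", {
  cts <- table2_fixture()
  e <- ppv(cts, "SWITCH_ARB", "DEFINITE")
  expect_equal(e$numerator, 101L)
  expect_equal(e$denominator, 180L)
  expect_equal(e$estimate, 101 / 180)
  expect_equal(ppv(cts, "SWITCH_ARB", "AT_LEAST_POSSIBLE")$numerator, 163L)
  expect_equal(ppv(cts, "SWITCH_ARB", "DEFINITE",
                   term_filter = "cough")$numerator, 83L)
  expect_error(ppv(cts, "SWITCH_ARB", "AT_LEAST_POSSIBLE",
                   term_filter = "cough"), "DEFINITE level")
  n <- npv(cts, "CONTINUATION_TOTAL", "AT_LEAST_POSSIBLE")
  expect_equal(n$numerator, 585L - 28L)
  expect_equal(npv(cts, "CONTINUATION_TOTAL",
                   "AT_LEAST_PROBABLE")$numerator, 585L - 28L - 112L)
  expect_error(npv(cts, "CONTINUATION_TOTAL", "DEFINITE"), "not defined")
  # zero numerator gives estimate 0 with a CI starting at 0
  tab <- cts$table
  tab[tab$category == "SWITCH_OTHER",
      c("definite_adr", "nothing_mentioned")] <- c(0L, 67L)
  e0 <- ppv(validation_counts(tab), "SWITCH_OTHER", "DEFINITE")
  expect_equal(e0$estimate, 0)
  expect_equal(e0$ci_low, 0)
  # zero denominator is an error
  tab$n[tab$category == "SWITCH_OTHER"] <- 0L
  tab[tab$category == "SWITCH_OTHER", -(1:2)] <- 0L
  expect_error(ppv(validation_counts(tab), "SWITCH_OTHER", "DEFINITE"),
               "zero denominator")
})

test_that("PPV is non-decreasing across ascertainment levels", {
  cts <- table2_fixture()
  for (g in c("SWITCH_ARB", "SWITCH_OTHER", "STOP", "SWITCHERS_TOTAL",
              "TOTAL_DISCONTINUATION")) {
    est <- vapply(ascertainment_levels(),
                  function(lv) ppv(cts, g, lv)$estimate, numeric(1))
    expect_true(all(diff(est) >= 0))
  }
})

test_that("the Wilson interval matches the score-equation root finder", {
  expect_equal(unname(wilson_interval(101, 180)),
               c(0.4881, 0.6316), tolerance = 1e-4)
  expect_equal(unname(wilson_interval(0, 50))[1], 0)
  expect_equal(unname(wilson_interval(50, 50))[2], 1)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    expect_equal(unname(wilson_interval(x, n)), oracle_wilson(x, n),
                 tolerance = 1e-9)
  }
  # interval contains the point estimate; width shrinks with n
  w <- function(x, n) diff(wilson_interval(x, n))
  expect_true(w(20, 40) > w(200, 400))
  ci <- wilson_interval(7, 19)
  expect_true(ci[1] <= 7 / 19 && 7 / 19 <= ci[2])
  expect_error(wilson_interval(5, 0), "denominator")
  expect_error(wilson_interval(-1, 10), "denominator")
  expect_error(wilson_interval(11, 10), "denominator")
})

test_that("alternative interval methods are available and sane", {
  cp <- binom_interval(101, 180, method = "clopper-pearson")
  wa <- binom_interval(101, 180, method = "wald")
  wi <- binom_interval(101, 180, method = "wilson")
  for (ci in list(cp, wa, wi)) {
    expect_true(ci[1] < 101 / 180 && 101 / 180 < ci[2])
  }
  # exact interval is at least as wide as Wilson
  expect_true(cp[2] - cp[1] >= wi[2] - wi[1])
  expect_equal(unname(binom_interval(0, 50,
                                     method = "clopper-pearson"))[1], 0)
  expect_equal(unname(binom_interval(50, 50,
                                     method = "clopper-pearson"))[2], 1)
})

test_that("control matching respects durations, uniqueness and the seed", {
  cases <- data.frame(patient_id = "case1", acei_duration_days = 300,
                      stringsAsFactors = FALSE)
  pool <- data.frame(patient_id = c("c250", "c400"),
                     acei_duration_days = c(250, 400),
                     stringsAsFactors = FALSE)
  m <- match_controls(cases, pool, seed = 5)
  expect_identical(m$pairs$control_id, "c400")
  expect_equal(m$pairs$evaluation_duration_days, 300)
  # two cases, one eligible control: longest case matched, other unmatched
  cases2 <- data.frame(patient_id = c("a300", "b350"),
                       acei_duration_days = c(300, 350),
                       stringsAsFactors = FALSE)
  pool2 <- data.frame(patient_id = "c400", acei_duration_days = 400,
                      stringsAsFactors = FALSE)
  m2 <- match_controls(cases2, pool2, seed = 5)
  expect_identical(m2$pairs$case_id, "b350")
  expect_identical(m2$unmatched, "a300")
  # determinism and no reuse on a larger random problem
  set.seed(2)
  cases3 <- data.frame(patient_id = sprintf("k%03d", 1:40),
                       acei_duration_days = sample(50:900, 40),
                       stringsAsFactors = FALSE)
  pool3 <- data.frame(patient_id = sprintf("q%03d", 1:60),
                      acei_duration_days = sample(50:900, 60),
                      stringsAsFactors = FALSE)
  m3 <- match_controls(cases3, pool3, seed = 77)
  m3b <- match_controls(cases3, pool3, seed = 77)
  expect_identical(m3, m3b)
  expect_false(any(duplicated(m3$pairs$control_id)))
  ctrl_dur <- pool3$acei_duration_days[match(m3$pairs$control_id,
                                             pool3$patient_id)]
  expect_true(all(ctrl_dur >= m3$pairs$evaluation_duration_days))
})

test_that("sensitivity and specificity count definite ADRs in matched sets", {
  case_cls <- c(rep("DEFINITE_ADR", 101), rep("NOTHING_MENTIONED", 79))
  ctrl_cls <- c(rep("DEFINITE_ADR", 9), rep("NOTHING_MENTIONED", 171))
  ss <- sensitivity_specificity(case_cls, ctrl_cls)
  expect_equal(ss$tp, 101)
  expect_equal(ss$fn, 9)
  expect_equal(ss$sensitivity$estimate, 101 / 110, tolerance = 1e-12)
  expect_equal(ss$specificity$estimate, 171 / 250, tolerance = 1e-12)
  # no definite ADR among controls -> perfect sensitivity
  ss2 <- sensitivity_specificity(c("DEFINITE_ADR", "PROBABLE_ADR"),
                                 rep("NOTHING_MENTIONED", 2))
  expect_equal(ss2$sensitivity$estimate, 1)
  expect_error(sensitivity_specificity(character(0), character(0)), "empty")
  expect_error(sensitivity_specificity("DEFINITE_ADR",
                                       rep("NOTHING_MENTIONED", 2)),
               "equal length")
})
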