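# Closed-form class distributions for the three kinds of test-positive
# patients the generator can produce. Window = before + after + 1 days
# (closed on both sides); background events are Poisson, so the chance of
# at least one probable-phrased background event in the window is
# 1 - exp(-rate * window).
branch_class_probs <- function(p, before_days, after_days) {
  W <- before_days + after_days + 1
  pbp <- 1 - exp(-p$background_rates[["probable"]] * W)
  pbn <- 1 - exp(-p$background_rates[["non_probable"]] * W)
  qd <- p$recording[["definite"]]
  qp <- p$recording[["probable"]]
  qr <- p$p_reason_recorded
  list(
    adr = c(definite = qd,
            probable = (1 - qd) * (1 - (1 - qp) * (1 - pbp)),
            nothing = (1 - qd) * (1 - qp) * (1 - pbp) * (1 - pbn)),
    nonadr = c(definite = 0,
               probable = (1 - qr) * pbp,
               nothing = (1 - qr) * (1 - pbp) * (1 - pbn)),
    spurious = c(definite = 0,
                 probable = pbp,
                 nothing = (1 - pbp) * (1 - pbn)))
}

# P(interruption length > gap) for the integer-uniform interruption draw
interruption_exceeds <- function(p, gap_days) {
  a <- p$interruption_range[1L]; b <- p$interruption_range[2L]
  min(1, max(0, (b - gap_days) / (b - a + 1)))
}

# generative weight of each branch inside a test-positive group
group_branch_weights <- function(p, group, gap_days) {
  wa <- p$p_adr * p$action_given_adr
  wn <- (1 - p$p_adr) * p$p_nonadr_discont * p$action_given_nonadr
  wspur <- (1 - p$p_adr) * (1 - p$p_nonadr_discont) * p$p_interruption *
    interruption_exceeds(p, gap_days)
  per_cat <- function(cat) {
    switch(cat,
      SWITCH_ARB = c(adr = unname(wa[["switch_arb"]]),
                     nonadr = unname(wn[["switch_arb"]]), spurious = 0),
      SWITCH_OTHER = c(adr = unname(wa[["switch_other"]]),
                       nonadr = unname(wn[["switch_other"]]), spurious = 0),
      STOP = c(adr = unname(wa[["stop"]]), nonadr = unname(wn[["stop"]]),
               spurious = wspur))
  }
  cats <- group_members(group)
  Reduce(`+`, lapply(cats, per_cat))
}

#' Closed-form expected positive predictive value of the generator
#'
#' Enumerates the discrete generative branches (ADR with each action,
#' non-ADR discontinuation, spurious long refill interruption) together
#' with the recording model and background event process, and returns the
#' conditional probability that a patient classified into the group carries
#' an adjudicated class inside the ascertainment level. Exact in the
#' absence of censoring; with the default equal ADR/non-ADR latency means,
#' censoring thins all branches at the same rate and the value remains
#' accurate (see the methods vignette).
#'
#' @param params A [cohort_params()] list.
#' @param group `SWITCH_ARB`, `SWITCH_OTHER`, `STOP`, `SWITCHERS_TOTAL` or
#'   `TOTAL_DISCONTINUATION`.
#' @param level One of [ascertainment_levels()].
#' @param gap_days Renewal gap the classifier will use (affects how many
#'   interrupted continuers land in the stop group).
#' @param before_days,after_days Adjudication window, as in
#'   [adjudicate_case()].
#' @param term_filter Optional ADR term (`level` must be `"DEFINITE"`), as
#'   in [ppv()].
#' @return Expected PPV as a proportion.
#' @export
expected_ppv <- function(params, group, level, gap_days = 90L,
                         before_days = 180L, after_days = 90L,
                         term_filter = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  group <- match.arg(group, c(test_positive_categories(),
                              "SWITCHERS_TOTAL", "TOTAL_DISCONTINUATION"))
  level <- match.arg(level, ascertainment_levels())
  w <- group_branch_weights(params, group, gap_days)
  if (sum(w) <= 0) stop("group ", group, " has zero probability under params",
                        call. = FALSE)
  cp <- branch_class_probs(params, before_days, after_days)
  if (!is.null(term_filter)) {
    if (level != "DEFINITE") {
      stop("term_filter is defined for the DEFINITE level only",
           call. = FALSE)
    }
    tf <- params$adr_terms[[term_filter]]
    hit <- vapply(cp, function(x) x[["definite"]] * tf, numeric(1))
  } else {
    hit <- vapply(cp, function(x) {
      switch(level,
        DEFINITE = x[["definite"]],
        AT_LEAST_PROBABLE = x[["definite"]] + x[["probable"]],
        AT_LEAST_POSSIBLE = x[["definite"]] + x[["probable"]] +
          x[["nothing"]])
    }, numeric(1))
  }
  sum(w * hit) / sum(w)
}

#' Closed-form expected negative predictive value (at-least-possible level)
#'
#' The only NPV with a closed form under the generator: background events
#' never produce a definite ADR, so the definite fraction among continuers
#' is the tolerated-ADR branch times its definite-recording probability.
#' The at-least-probable NPV depends on each patient's episode length
#' through the background process and has no closed form; it is checked
#' empirically instead.
#'
#' @inheritParams expected_ppv
#' @return Expected NPV (proportion) for the total continuation group.
#' @export
expected_npv <- function(params, level = "AT_LEAST_POSSIBLE",
                         gap_days = 90L) {
  stopifnot(inherits(params, "cohort_params"))
  if (!identical(level, "AT_LEAST_POSSIBLE")) {
    stop("closed form exists only for the AT_LEAST_POSSIBLE level",
         call. = FALSE)
  }
  p <- params
  w_tol <- p$p_adr * p$action_given_adr[["continue"]]
  w_plain <- (1 - p$p_adr) * (1 - p$p_nonadr_discont) *
    (1 - p$p_interruption * interruption_exceeds(p, gap_days))
  1 - w_tol * p$recording_tolerated[["definite"]] / (w_tol + w_plain)
}
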