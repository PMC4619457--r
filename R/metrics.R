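#' Construct a validation counts table
#'
#' The category-by-adjudication-class contingency table underlying every
#' accuracy estimate: one row per prescription-pattern category with the
#' category size `n` and counts of each patient class, plus a long table of
#' definite-ADR counts by ADR term (for term-restricted predictive values
#' such as cough).
#'
#' @param table Data frame with columns `category`, `n`, `definite_adr`,
#'   `definite_non_adr`, `probable_adr`, `non_probable_hp`,
#'   `nothing_mentioned`; one row per category in [pattern_categories()].
#' @param definite_terms Optional data frame `category`, `adr_term`, `count`
#'   breaking down the definite ADRs.
#' @return Object of class `validation_counts`.
#' @export
validation_counts <- function(table, definite_terms = NULL) {
  need <- c("category", "n", "definite_adr", "definite_non_adr",
            "probable_adr", "non_probable_hp", "nothing_mentioned")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) stop("missing columns: ",
                              paste(miss, collapse = ", "), call. = FALSE)
  lev <- pattern_categories()
  if (!setequal(table$category, lev) || nrow(table) != length(lev)) {
    stop("table must have exactly one row per pattern category",
         call. = FALSE)
  }
  table <- table[match(lev, table$category), need, drop = FALSE]
  rownames(table) <- NULL
  cls_sum <- rowSums(table[, need[-(1:2)]])
  if (any(cls_sum != table$n)) {
    stop("class counts do not sum to category n for: ",
         paste(table$category[cls_sum != table$n], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(definite_terms)) {
    agg <- tapply(definite_terms$count, definite_terms$category, sum)
    chk <- table$definite_adr[match(names(agg), table$category)]
    if (any(agg > chk)) {
      stop("definite term counts exceed definite ADR counts", call. = FALSE)
    }
  }
  structure(list(table = table, definite_terms = definite_terms),
            class = "validation_counts")
}

#' @export
print.validation_counts <- function(x, ...) {
  cat("Validation counts (N =", sum(x$table$n), "patients)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tabulate pattern-by-adjudication counts for a cohort
#'
#' @param patterns Data frame from [classify_patterns()].
#' @param adjudications Data frame from [adjudicate_cohort()]; must cover
#'   exactly the same patients.
#' @return A [validation_counts()] object.
#' @export
tabulate_validation <- function(patterns, adjudications) {
  if (!setequal(patterns$patient_id, adjudications$patient_id) ||
      nrow(patterns) != nrow(adjudications)) {
    stop("patterns and adjudications must cover the same patients",
         call. = FALSE)
  }
  m <- merge(patterns[, c("patient_id", "category")],
             adjudications[, c("patient_id", "patient_class", "adr_term")],
             by = "patient_id")
  lev <- pattern_categories()
  cat_f <- factor(m$category, lev)
  tab <- table(cat_f, factor(m$patient_class, patient_classes()))
  out <- data.frame(category = lev, n = as.integer(table(cat_f)),
                    definite_adr = as.integer(tab[, "DEFINITE_ADR"]),
                    definite_non_adr = as.integer(tab[, "DEFINITE_NON_ADR"]),
                    probable_adr = as.integer(tab[, "PROBABLE_ADR"]),
                    non_probable_hp = as.integer(tab[, "NON_PROBABLE_HP"]),
                    nothing_mentioned =
                      as.integer(tab[, "NOTHING_MENTIONED"]),
                    stringsAsFactors = FALSE)
  def <- m[m$patient_class == "DEFINITE_ADR" & !is.na(m$adr_term), ,
           drop = FALSE]
  terms <- if (nrow(def) > 0L) {
    agg <- aggregate(list(count = rep(1L, nrow(def))),
                     by = list(category = def$category,
                               adr_term = def$adr_term), FUN = sum)
    agg[order(agg$category, agg$adr_term), , drop = FALSE]
  } else NULL
  validation_counts(out, terms)
}

# margin groups available on top of the six raw categories
margin_groups <- function() {
  c("SWITCHERS_TOTAL", "TOTAL_DISCONTINUATION",
    "CONTINUATION_TOTAL", "CONTINUATION_MINUS_DEATH")
}

group_members <- function(group) {
  switch(group,
    SWITCHERS_TOTAL = c("SWITCH_ARB", "SWITCH_OTHER"),
    TOTAL_DISCONTINUATION = c("SWITCH_ARB", "SWITCH_OTHER", "STOP"),
    CONTINUATION_TOTAL = continuation_categories(),
    CONTINUATION_MINUS_DEATH = c("CONT_END_OF_STUDY", "CONT_OUT_OF_STUDY"),
    group)
}

group_counts <- function(counts, group) {
  stopifnot(inherits(counts, "validation_counts"))
  members <- group_members(group)
  if (!all(members %in% counts$table$category)) {
    stop("unknown group: ", group, call. = FALSE)
  }
  sub <- counts$table[counts$table$category %in% members, , drop = FALSE]
  colSums(sub[, -1L, drop = FALSE])
}

accuracy_estimate <- function(numerator, denominator, conf_level = 0.95,
                              ci_method = "wilson", label = NULL) {
  ci <- binom_interval(numerator, denominator, conf_level, ci_method)
  structure(list(numerator = numerator, denominator = denominator,
                 estimate = numerator / denominator,
                 ci_low = ci[[1L]], ci_high = ci[[2L]],
                 conf_level = conf_level, ci_method = ci_method,
                 label = label),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("%s: %d/%d = %.1f%% (%g%% CI %.1f-%.1f, %s)\n",
              if (is.null(x$label)) "proportion" else x$label,
              x$numerator, x$denominator, 100 * x$estimate,
              100 * x$conf_level, 100 * x$ci_low, 100 * x$ci_high,
              x$ci_method))
  invisible(x)
}

#' Positive predictive value of a test-positive prescription pattern
#'
#' The proportion of a test-positive group (stoppers, switchers, or their
#' margins) whose adjudicated class falls in the requested ascertainment
#' level. With `term_filter` the numerator is restricted to definite ADRs
#' of that term (e.g. `"cough"`), in which case `level` must be
#' `"DEFINITE"`.
#'
#' @param counts A [validation_counts()] object.
#' @param group One of `SWITCH_ARB`, `SWITCH_OTHER`, `STOP`,
#'   `SWITCHERS_TOTAL`, `TOTAL_DISCONTINUATION`.
#' @param level One of [ascertainment_levels()].
#' @param term_filter Optional ADR term restricting the numerator.
#' @param conf_level,ci_method Confidence level and interval method, see
#'   [binom_interval()].
#' @return An `accuracy_estimate` (numerator, denominator, estimate, CI).
#' @export
ppv <- function(counts, group, level, term_filter = NULL,
                conf_level = 0.95, ci_method = "wilson") {
  group <- match.arg(group, c(test_positive_categories(),
                              "SWITCHERS_TOTAL", "TOTAL_DISCONTINUATION"))
  level <- match.arg(level, ascertainment_levels())
  g <- group_counts(counts, group)
  if (g[["n"]] == 0L) stop("zero denominator for group ", group,
                           call. = FALSE)
  if (!is.null(term_filter)) {
    if (level != "DEFINITE") {
      stop("term_filter is defined for the DEFINITE level only",
           call. = FALSE)
    }
    dt <- counts$definite_terms
    if (is.null(dt)) stop("counts carry no definite term breakdown",
                          call. = FALSE)
    sel <- dt$category %in% group_members(group) & dt$adr_term == term_filter
    num <- sum(dt$count[sel])
  } else {
    num <- switch(level,
      DEFINITE = g[["definite_adr"]],
      AT_LEAST_PROBABLE = g[["definite_adr"]] + g[["probable_adr"]],
      AT_LEAST_POSSIBLE = g[["definite_adr"]] + g[["probable_adr"]] +
        g[["nothing_mentioned"]])
  }
  accuracy_estimate(num, g[["n"]], conf_level, ci_method,
                    label = paste0("PPV ", group, " ", level,
                                   if (!is.null(term_filter))
                                     paste0(" [", term_filter, "]") else ""))
}

#' Negative predictive value of a continuation subgroup
#'
#' Probable and possible ADRs are undefined for continuers (there is no
#' switch/stop date), so the NPV deducts recorded ADR mentions from the
#' subgroup size: at the at-least-possible level only definite ADRs are
#' deducted; at the at-least-probable level definite and probable ADRs are
#' deducted. A definite-only NPV is not defined.
#'
#' @param counts A [validation_counts()] object.
#' @param subgroup One of `CONT_END_OF_STUDY`, `CONT_OUT_OF_STUDY`,
#'   `CONT_DEATH`, `CONTINUATION_MINUS_DEATH`, `CONTINUATION_TOTAL`.
#' @param level `"AT_LEAST_POSSIBLE"` or `"AT_LEAST_PROBABLE"`.
#' @inheritParams ppv
#' @return An `accuracy_estimate`.
#' @export
npv <- function(counts, subgroup, level, conf_level = 0.95,
                ci_method = "wilson") {
  subgroup <- match.arg(subgroup, c(continuation_categories(),
                                    "CONTINUATION_MINUS_DEATH",
                                    "CONTINUATION_TOTAL"))
  if (identical(level, "DEFINITE")) {
    stop("NPV is not defined at the DEFINITE level", call. = FALSE)
  }
  level <- match.arg(level, c("AT_LEAST_POSSIBLE", "AT_LEAST_PROBABLE"))
  g <- group_counts(counts, subgroup)
  if (g[["n"]] == 0L) stop("zero denominator for subgroup ", subgroup,
                           call. = FALSE)
  ded <- g[["definite_adr"]] +
    if (level == "AT_LEAST_PROBABLE") g[["probable_adr"]] else 0L
  accuracy_estimate(g[["n"]] - ded, g[["n"]], conf_level, ci_method,
                    label = paste("NPV", subgroup, level))
}

#' Binomial confidence intervals
#'
#' `wilson_interval()` is the two-sided Wilson score interval (inversion of
#' the normal-approximation score test), which reproduces the published
#' intervals and behaves well near 0 and 1. `binom_interval()` additionally
#' offers the exact Clopper-Pearson interval and the Wald interval.
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @param method `"wilson"`, `"clopper-pearson"`, or `"wald"`.
#' @return Named numeric vector `c(ci_low, ci_high)` on the proportion
#'   scale.
#' @examples
#' wilson_interval(101, 180)  # c(0.488, 0.632)
#' @export
wilson_interval <- function(numerator, denominator, conf_level = 0.95) {
  check_counts(numerator, denominator)
  z <- stats::qnorm((1 + conf_level) / 2)
  n <- denominator
  p <- numerator / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ci_low = max(0, centre - half), ci_high = min(1, centre + half))
}

#' @rdname wilson_interval
#' @export
binom_interval <- function(numerator, denominator, conf_level = 0.95,
                           method = c("wilson", "clopper-pearson", "wald")) {
  method <- match.arg(method)
  check_counts(numerator, denominator)
  x <- numerator; n <- denominator
  alpha <- 1 - conf_level
  switch(method,
    wilson = wilson_interval(x, n, conf_level),
    `clopper-pearson` = c(
      ci_low = if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      ci_high = if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)),
    wald = {
      p <- x / n
      z <- stats::qnorm(1 - alpha / 2)
      hw <- z * sqrt(p * (1 - p) / n)
      c(ci_low = max(0, p - hw), ci_high = min(1, p + hw))
    })
}

check_counts <- function(numerator, denominator) {
  if (length(numerator) != 1L || length(denominator) != 1L ||
      !is.finite(numerator) || !is.finite(denominator) ||
      denominator <= 0 || numerator < 0 || numerator > denominator) {
    stop("need 0 <= numerator <= denominator, denominator > 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Match continuation controls to test-positive cases by treatment duration
#'
#' For each test-positive case a continuation control is drawn uniformly at
#' random (seeded) among unused continuers whose ACEI duration is at least
#' the case's duration, so the control's records can be searched over the
#' same time course. Cases are processed in descending duration order
#' (longest cases face the scarcest pool); controls are used at most once;
#' cases without an eligible control are reported unmatched.
#'
#' @param cases Data frame with `patient_id` and `acei_duration_days` for
#'   the test-positive patients.
#' @param continuers Data frame with `patient_id`, `acei_start_date` and
#'   `acei_duration_days` for the continuation pool.
#' @param seed Integer seed making the pairing reproducible.
#' @return List with `pairs` (`case_id`, `control_id`,
#'   `evaluation_duration_days`) and `unmatched` (case ids).
#' @export
match_controls <- function(cases, continuers, seed = 1L) {
  ord <- order(-cases$acei_duration_days, cases$patient_id)
  cs <- cases[ord, , drop = FALSE]
  pool_dur <- continuers$acei_duration_days
  used <- rep(FALSE, nrow(continuers))
  case_id <- character(0); control_id <- character(0); dur <- numeric(0)
  unmatched <- character(0)
  with_seed(seed, {
    for (i in seq_len(nrow(cs))) {
      elig <- which(!used & pool_dur >= cs$acei_duration_days[i])
      if (length(elig) == 0L) {
        unmatched <- c(unmatched, cs$patient_id[i])
      } else {
        pick <- if (length(elig) == 1L) elig else
          elig[sample.int(length(elig), 1L)]
        used[pick] <- TRUE
        case_id <- c(case_id, cs$patient_id[i])
        control_id <- c(control_id, continuers$patient_id[pick])
        dur <- c(dur, cs$acei_duration_days[i])
      }
    }
  })
  list(pairs = data.frame(case_id = case_id, control_id = control_id,
                          evaluation_duration_days = dur,
                          stringsAsFactors = FALSE),
       unmatched = unmatched)
}

#' Sensitivity and specificity from matched case/control adjudications
#'
#' Computed over equal-length matched sets considering definite ADRs only:
#' true positives are cases adjudicated `DEFINITE_ADR`, false negatives are
#' controls adjudicated `DEFINITE_ADR`, and so on. Wilson (or requested)
#' intervals are attached.
#'
#' @param case_classes,control_classes Character vectors of patient classes
#'   for the matched cases and controls, in matching order.
#' @inheritParams ppv
#' @return List with `sensitivity` and `specificity` accuracy estimates and
#'   the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
sensitivity_specificity <- function(case_classes, control_classes,
                                    conf_level = 0.95,
                                    ci_method = "wilson") {
  if (length(case_classes) == 0L) {
    stop("empty matched sets", call. = FALSE)
  }
  if (length(case_classes) != length(control_classes)) {
    stop("matched sets must have equal length", call. = FALSE)
  }
  tp <- sum(case_classes == "DEFINITE_ADR")
  fp <- sum(case_classes != "DEFINITE_ADR")
  fn <- sum(control_classes == "DEFINITE_ADR")
  tn <- sum(control_classes != "DEFINITE_ADR")
  list(sensitivity = accuracy_estimate(tp, tp + fn, conf_level, ci_method,
                                       label = "sensitivity"),
       specificity = accuracy_estimate(tn, tn + fp, conf_level, ci_method,
                                       label = "specificity"),
       tp = tp, fp = fp, fn = fn, tn = tn)
}
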