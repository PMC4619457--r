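#' Published six-month validation counts fixture
#'
#' The category-by-adjudication contingency table of a published Dutch
#' population-based validation at the six-month renewal gap (1132 ACEI
#' starters), keyed in verbatim: 180 switchers to ARB, 106 switchers to
#' other antihypertensives, 261 stoppers and 585 continuers subdivided by
#' the reason follow-up ended, with definite ADR counts broken down by term
#' (cough, angioedema, other). Feeding this fixture through [ppv()] and
#' [npv()] reproduces the published predictive values without patient-level
#' data ("counts mode").
#'
#' @return A [validation_counts()] object.
#' @export
table2_fixture <- function() {
  tab <- data.frame(
    category = c("SWITCH_ARB", "SWITCH_OTHER", "STOP",
                 "CONT_OUT_OF_STUDY", "CONT_DEATH", "CONT_END_OF_STUDY"),
    n = c(180L, 106L, 261L, 167L, 119L, 299L),
    definite_adr = c(101L, 42L, 51L, 7L, 5L, 16L),
    definite_non_adr = c(10L, 10L, 28L, 0L, 0L, 0L),
    probable_adr = c(22L, 20L, 43L, 35L, 21L, 56L),
    non_probable_hp = c(7L, 9L, 7L, 1L, 4L, 9L),
    nothing_mentioned = c(40L, 25L, 132L, 124L, 89L, 218L),
    stringsAsFactors = FALSE)
  terms <- data.frame(
    category = rep(tab$category, each = 3L),
    adr_term = rep(c("cough", "angioedema", "other"), times = 6L),
    count = c(83L, 3L, 15L,
              25L, 1L, 16L,
              35L, 1L, 15L,
              4L, 0L, 3L,
              3L, 1L, 1L,
              13L, 1L, 2L),
    stringsAsFactors = FALSE)
  validation_counts(tab, terms)
}
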