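#' Default ATC prefix to antihypertensive drug-class map
#'
#' Maps WHO ATC code prefixes to the drug classes used in the pattern
#' definitions: ACEIs (C09A plain, C09B combinations), ARBs (C09C, C09D),
#' beta blockers (C07), calcium channel blockers (C08), diuretics (C03) and
#' other antihypertensives (C02). Combination products count as exposure to
#' the class of their ACEI/ARB component.
#'
#' @return A data.frame with columns `prefix` and `class`.
#' @seealso [classify_atc()]
#' @export
atc_class_map <- function() {
  data.frame(
    prefix = c("C09A", "C09B", "C09C", "C09D", "C07", "C08", "C03", "C02"),
    class  = c("ACEI", "ACEI", "ARB", "ARB", "BETA_BLOCKER", "CCB",
               "DIURETIC", "OTHER_ANTIHYPERTENSIVE"),
    stringsAsFactors = FALSE
  )
}

#' Classify an ATC code into an antihypertensive drug class
#'
#' Longest-prefix-first lookup of an ATC code against a prefix map. Codes
#' matching no prefix (e.g. statins) return `NA`.
#'
#' @param atc_code Character vector of ATC codes (3-7 characters).
#' @param class_map Prefix map as returned by [atc_class_map()]; prefixes
#'   must be mutually non-nested.
#' @return Character vector of drug classes, `NA` where no prefix matches.
#' @examples
#' classify_atc(c("C09AA05", "C09DA01", "C10AA01"))
#' @export
classify_atc <- function(atc_code, class_map = atc_class_map()) {
  if (length(atc_code) == 0L) return(character(0))
  atc_code <- as.character(atc_code)
  if (anyNA(atc_code) || any(!nzchar(atc_code))) {
    stop("atc_code must be non-empty", call. = FALSE)
  }
  map <- class_map[order(-nchar(class_map$prefix)), , drop = FALSE]
  out <- rep(NA_character_, length(atc_code))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(out) & startsWith(atc_code, map$prefix[i])
    out[hit] <- map$class[i]
  }
  out
}
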