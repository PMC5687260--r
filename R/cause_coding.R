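# ICD-10 range parsing and cause-category classification.
#
# Disease categories are defined by sets of 3-character ICD-10 roots
# (letter + two digits). Classification is root-level only: the 4th-character
# detail of a code never changes its category.

#' Cause-of-death category vocabulary
#'
#' The four-category vocabulary used throughout the package: the three audited
#' disease categories plus the complement category `"other"`.
#'
#' @return character vector `c("heart", "cancer", "renal", "other")`.
#' @export
cause_categories <- function() c("heart", "cancer", "renal", "other")

DISEASE_CATEGORIES <- c("heart", "cancer", "renal")

# Normalise the range separator: en dash, em dash and minus sign -> hyphen.
normalize_dashes <- function(x) gsub("[–—−]", "-", x)

#' Parse an ICD-10 code-range specification
#'
#' Expands a comma-separated list of 3-character ICD-10 roots and inclusive
#' hyphenated ranges (e.g. `"I00-I09,I11,I13,I20-I51"`) into the full set of
#' roots it covers. Both the ASCII hyphen and the en dash are accepted as the
#' range separator, so category definitions can be pasted verbatim from
#' published reports.
#'
#' @param spec character scalar, e.g. `"C00-C97"` or `"N00-N07,N17-N19,N25-N27"`.
#' @param category the category label the set defines; one of
#'   [cause_categories()].
#' @return an object of class `icd_codeset`: a list with elements `category`
#'   and `prefixes` (sorted character vector of 3-character roots).
#' @examples
#' length(parse_icd10_range("C00-C97", "cancer")$prefixes)  # 98
#' parse_icd10_range("I11", "heart")$prefixes               # "I11"
#' @export
parse_icd10_range <- function(spec, category) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec) || !nzchar(spec))
    stop_validation("'spec' must be a single non-empty character string")
  category <- match.arg(category, cause_categories())
  tokens <- trimws(strsplit(normalize_dashes(spec), ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop_validation("empty ICD-10 range specification: '%s'", spec)
  prefixes <- character(0)
  for (tok in tokens) {
    if (grepl("^[A-Z][0-9]{2}$", tok)) {
      prefixes <- c(prefixes, tok)
    } else if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", tok)) {
      a <- substr(tok, 1, 3)
      b <- substr(tok, 5, 7)
      if (substr(a, 1, 1) != substr(b, 1, 1))
        stop_validation("range endpoints use different letters: '%s'", tok)
      lo <- as.integer(substr(a, 2, 3))
      hi <- as.integer(substr(b, 2, 3))
      if (hi < lo)
        stop_validation("reversed ICD-10 range (end before start): '%s'", tok)
      prefixes <- c(prefixes, sprintf("%s%02d", substr(a, 1, 1), lo:hi))
    } else {
      stop_validation("malformed ICD-10 code or range: '%s'", tok)
    }
  }
  structure(list(category = category,
                 prefixes = sort(unique(prefixes))),
            class = "icd_codeset")
}

#' @export
print.icd_codeset <- function(x, ...) {
  cat(sprintf("<icd_codeset> %s: %d roots (%s ... %s)\n",
              x$category, length(x$prefixes),
              x$prefixes[1], x$prefixes[length(x$prefixes)]))
  invisible(x)
}

#' Default disease-category code sets
#'
#' The packaged root-level ICD-10 definitions of the three audited disease
#' categories: heart disease I00-I09, I11, I13, I20-I51; cancer C00-C97;
#' renal disease N00-N07, N17-N19, N25-N27. Anything else is `"other"`.
#' Benchmark studies that redefine categories can pass their own code sets to
#' [classify_cause()] and [build_pairs()].
#'
#' @return named list of `icd_codeset` objects (`heart`, `cancer`, `renal`).
#' @export
default_codesets <- function() {
  list(
    heart  = parse_icd10_range("I00-I09,I11,I13,I20-I51", "heart"),
    cancer = parse_icd10_range("C00-C97", "cancer"),
    renal  = parse_icd10_range("N00-N07,N17-N19,N25-N27", "renal")
  )
}

# prefix -> category lookup; errors if the defined sets overlap.
codeset_lookup <- function(codesets) {
  if (!length(codesets)) stop_validation("'codesets' is empty")
  prefixes <- unlist(lapply(codesets, function(cs) {
    if (!inherits(cs, "icd_codeset"))
      stop_validation("every element of 'codesets' must be an icd_codeset")
    cs$prefixes
  }), use.names = FALSE)
  categories <- unlist(lapply(codesets, function(cs)
    rep(cs$category, length(cs$prefixes))), use.names = FALSE)
  dup <- duplicated(prefixes)
  if (any(dup))
    stop_validation("code sets are not disjoint: root '%s' appears in more than one category",
                    prefixes[dup][1])
  stats::setNames(categories, prefixes)
}

#' Classify ICD-10 codes into cause categories
#'
#' Maps full ICD-10 codes (root optionally followed by `"."` and subcode
#' characters) to the category whose prefix set contains the 3-character root.
#' Codes outside every defined set — including unusual but syntactically valid
#' roots — map to `"other"`, since screening data may contain any code.
#'
#' @param code character vector of ICD-10 codes, e.g. `"I21.9"`, `"N18"`.
#' @param codesets named list of [icd_codeset][parse_icd10_range] objects;
#'   defaults to [default_codesets()]. Sets must be pairwise disjoint.
#' @return character vector of categories, same length as `code`.
#' @examples
#' classify_cause(c("I21.9", "N18.5", "J44.9"))  # heart, renal, other
#' @export
classify_cause <- function(code, codesets = default_codesets()) {
  if (!is.character(code))
    stop_validation("'code' must be a character vector")
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", code)
  if (any(bad))
    stop_validation("syntactically invalid ICD-10 code: '%s'", code[bad][1])
  lookup <- codeset_lookup(codesets)
  root <- substr(code, 1, 3)
  out <- unname(lookup[root])
  out[is.na(out)] <- "other"
  out
}
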