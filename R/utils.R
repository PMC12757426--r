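# Internal helpers shared across modules.

#' Normalize a drug name
#'
#' Uppercases, strips every character outside `[A-Z0-9 ]`, and collapses
#' runs of whitespace — the standard cleaning applied to FAERS `DRUGNAME`
#' strings so that salt forms and trade-name decorations compare equal.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @examples
#' normalize_drug_name("Voquezna® (vonoprazan)")
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(enc2utf8(as.character(x)))
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Pad a FAERS date string to 8 digits. Partial dates (YYYY or YYYYMM) are
# zero-padded to the first day/month so they still order deterministically
# in deduplication; anything unparseable becomes NA.
pad_faers_date <- function(x) {
  x <- gsub("[^0-9]", "", as.character(x))
  x[!nzchar(x)] <- NA_character_
  ok4 <- !is.na(x) & nchar(x) == 4L
  ok6 <- !is.na(x) & nchar(x) == 6L
  x[ok4] <- paste0(x[ok4], "0101")
  x[ok6] <- paste0(x[ok6], "01")
  x[!is.na(x) & nchar(x) != 8L] <- NA_character_
  x
}

# Parse an 8-digit FAERS date into a Date; partial dates are NA (they are
# padded only for ordering, never used for interval arithmetic).
parse_faers_date_full <- function(x) {
  x <- gsub("[^0-9]", "", as.character(x))
  x[!nzchar(x) | nchar(x) != 8L] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

# Format a proportion the way descriptive tables print it: one decimal place
# on the percent scale.
format_pct <- function(num, den) {
  sprintf("%.1f%%", 100 * num / den)
}

#' Descriptive proportion
#'
#' Percentage of a count over a denominator at one-decimal printing
#' precision, as used in descriptive baseline tables.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @return numeric percentage rounded to one decimal.
#' @examples
#' describe_proportion(612, 987) # 62.0
#' @export
describe_proportion <- function(num, den) {
  stopifnot(den > 0, num >= 0, num <= den)
  round(100 * num / den, 1)
}
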