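# Parsed SDRF column headers.
#
# An SDRF header is either a prefix-only identifier column ("source name",
# "assay name") or a bracketed attribute column ("characteristics[organism]",
# "comment[data file]", "factor value[phenotype]"). Headers may repeat; the
# occurrence index (1-based, left to right) distinguishes repeats.

SDRF_CATEGORIES <- c("SOURCE_NAME", "CHARACTERISTICS", "COMMENT",
                     "FACTOR_VALUE", "ASSAY_NAME")

#' Construct a column key
#'
#' A `column_key` identifies one SDRF column: its category, its bracketed
#' attribute (empty for the `source name` / `assay name` identifier columns)
#' and its occurrence index among identically named columns.
#'
#' @param category One of `"SOURCE_NAME"`, `"CHARACTERISTICS"`, `"COMMENT"`,
#'   `"FACTOR_VALUE"`, `"ASSAY_NAME"`.
#' @param attribute Lower-cased attribute text; must be empty exactly when
#'   `category` is `SOURCE_NAME` or `ASSAY_NAME`.
#' @param occurrence Positive integer, 1-based index among columns sharing the
#'   same canonical header.
#' @return An object of class `column_key`.
#' @export
#' @examples
#' column_key("CHARACTERISTICS", "organism")
#' column_key("ASSAY_NAME")
column_key <- function(category, attribute = "", occurrence = 1L) {
  category <- match.arg(category, SDRF_CATEGORIES)
  attribute <- as.character(attribute)
  occurrence <- as.integer(occurrence)
  if (is.na(occurrence) || occurrence < 1L) {
    stop("`occurrence` must be a positive integer", call. = FALSE)
  }
  prefix_only <- category %in% c("SOURCE_NAME", "ASSAY_NAME")
  if (prefix_only && nzchar(attribute)) {
    stop(sprintf("category %s takes no attribute", category), call. = FALSE)
  }
  if (!prefix_only && !nzchar(attribute)) {
    stop(sprintf("category %s requires an attribute", category), call. = FALSE)
  }
  if (attribute != squish(attribute) || attribute != tolower(attribute)) {
    stop("`attribute` must be lower-cased with normalized whitespace",
         call. = FALSE)
  }
  structure(
    list(category = category, attribute = attribute, occurrence = occurrence),
    class = "column_key"
  )
}

#' @export
print.column_key <- function(x, ...) {
  cat(sprintf("<column_key> %s (occurrence %d)\n",
              format_column_header(x), x$occurrence))
  invisible(x)
}

# collapse internal whitespace runs and trim ends
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

sdrf_parse_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sdrf_parse_error", "sdrf_error")))
}

#' Parse an SDRF column header
#'
#' Matching is case-insensitive and tolerant of whitespace between the prefix
#' and the opening bracket and inside the brackets (both `characteristics [x]`
#' and `characteristics[x]` occur in the wild); the parsed attribute is
#' case-folded and whitespace-normalized. The occurrence index defaults to 1;
#' [read_sdrf()] renumbers repeated headers left to right.
#'
#' @param header A single non-empty header string.
#' @return A [column_key()].
#' @export
#' @examples
#' parse_column_header("characteristics [organism part]")
#' parse_column_header("factor value[tissue]")
parse_column_header <- function(header) {
  if (!is.character(header) || length(header) != 1L || is.na(header) ||
      !nzchar(trimws(header))) {
    sdrf_parse_error("column header must be a non-empty string")
  }
  raw <- trimws(header)
  if (!grepl("[", raw, fixed = TRUE)) {
    plain <- squish(tolower(raw))
    if (plain == "source name") return(column_key("SOURCE_NAME"))
    if (plain == "assay name") return(column_key("ASSAY_NAME"))
    sdrf_parse_error("unrecognized column header '%s'", header)
  }
  open <- regexpr("[", raw, fixed = TRUE)[1]
  prefix <- squish(tolower(substr(raw, 1L, open - 1L)))
  category <- switch(prefix,
    "characteristics" = "CHARACTERISTICS",
    "comment" = "COMMENT",
    "factor value" = "FACTOR_VALUE",
    sdrf_parse_error("unknown column prefix '%s' in header '%s'",
                     prefix, header)
  )
  if (substr(raw, nchar(raw), nchar(raw)) != "]") {
    sdrf_parse_error("missing closing bracket in header '%s'", header)
  }
  attribute <- squish(tolower(substr(raw, open + 1L, nchar(raw) - 1L)))
  if (!nzchar(attribute)) {
    sdrf_parse_error("empty attribute in header '%s'", header)
  }
  column_key(category, attribute)
}

#' Render the canonical form of a column header
#'
#' The canonical rendering is lower-case with no whitespace before the bracket
#' (`characteristics[organism part]`); parsing a canonical header and
#' formatting it back is the identity.
#'
#' @param key A [column_key()].
#' @return A header string.
#' @export
#' @examples
#' format_column_header(column_key("COMMENT", "fraction identifier"))
format_column_header <- function(key) {
  stopifnot(inherits(key, "column_key"))
  switch(key$category,
    SOURCE_NAME = "source name",
    ASSAY_NAME = "assay name",
    CHARACTERISTICS = sprintf("characteristics[%s]", key$attribute),
    COMMENT = sprintf("comment[%s]", key$attribute),
    FACTOR_VALUE = sprintf("factor value[%s]", key$attribute)
  )
}

# canonical identity of a column within a table, occurrence-aware
column_id <- function(key) {
  sprintf("%s#%d", format_column_header(key), key$occurrence)
}

keys_equal <- function(a, b) {
  a$category == b$category && a$attribute == b$attribute &&
    a$occurrence == b$occurrence
}
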