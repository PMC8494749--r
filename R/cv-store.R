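# Offline controlled-vocabulary store.
#
# Term validation runs against bundled snapshot files instead of a live
# ontology-lookup service: each snapshot is a 3-column TSV
# (accession, label, ontology prefix). The bundled set under
# inst/extdata/cv/ is a small curated synthetic subset of the ontologies
# commonly used in SDRF annotation (EFO, PSI-MS, UNIMOD, NCBITaxon, UBERON,
# MONDO, PATO) — enough for validation and testing, not a full export.

#' Load controlled-vocabulary snapshot files
#'
#' Each file is a 3-column tab-delimited snapshot: accession, label, ontology
#' prefix. Files are unioned in order; on an accession collision the later
#' file wins and the override is logged via [message()]. Lines that are empty
#' or start with `#` are skipped.
#'
#' @param paths Character vector of snapshot file paths (may be empty).
#' @return An object of class `cv_store`.
#' @export
#' @examples
#' store <- load_cv(cv_snapshot_paths())
#' lookup_accession(store, "UNIMOD:35")
load_cv <- function(paths = character(0)) {
  label_by_acc <- character(0)
  prefix_by_acc <- character(0)
  for (path in paths) {
    lines <- read_utf8_lines(path)
    for (i in seq_along(lines)) {
      line <- lines[i]
      if (!nzchar(trimws(line)) || startsWith(line, "#")) next
      cells <- split_tsv_line(line)
      if (length(cells) != 3L || !all(nzchar(trimws(cells)))) {
        sdrf_parse_error("%s, line %d: expected 3 non-empty tab-separated fields",
                         path, i)
      }
      acc <- trimws(cells[1])
      if (acc %in% names(label_by_acc)) {
        message(sprintf("cv snapshot %s overrides accession %s ('%s' -> '%s')",
                        basename(path), acc, label_by_acc[[acc]],
                        trimws(cells[2])))
      }
      label_by_acc[acc] <- trimws(cells[2])
      prefix_by_acc[acc] <- trimws(cells[3])
    }
  }
  accs <- names(label_by_acc)
  if (is.null(accs)) accs <- character(0)
  acc_by_key <- stats::setNames(
    accs,
    paste(tolower(prefix_by_acc), tolower(label_by_acc), sep = "\x1f"))
  structure(list(label_by_acc = label_by_acc, prefix_by_acc = prefix_by_acc,
                 acc_by_key = acc_by_key),
            class = "cv_store")
}

#' @export
print.cv_store <- function(x, ...) {
  cat(sprintf("<cv_store> %d terms from %d ontolog%s\n",
              length(x$label_by_acc), length(unique(x$prefix_by_acc)),
              if (length(unique(x$prefix_by_acc)) == 1) "y" else "ies"))
  invisible(x)
}

#' Paths of the bundled CV snapshot files
#' @return Character vector of file paths.
#' @export
cv_snapshot_paths <- function() {
  dir <- system.file("extdata", "cv", package = "sdrftab")
  list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
}

#' Load the bundled CV snapshots
#' @return A `cv_store` over every bundled snapshot file.
#' @export
default_cv_store <- function() {
  load_cv(cv_snapshot_paths())
}

#' Look up a term by accession
#'
#' Case-sensitive accession lookup; an unknown accession yields `NULL`,
#' never an error.
#'
#' @param store A `cv_store`.
#' @param accession Accession text, e.g. `"UNIMOD:35"`.
#' @return `list(label =, prefix =)` or `NULL`.
#' @export
lookup_accession <- function(store, accession) {
  stopifnot(inherits(store, "cv_store"))
  if (!accession %in% names(store$label_by_acc)) return(NULL)
  list(label = unname(store$label_by_acc[[accession]]),
       prefix = unname(store$prefix_by_acc[[accession]]))
}

#' Find a term's accession by label
#'
#' Case-insensitive label match within one ontology prefix.
#'
#' @param store A `cv_store`.
#' @param prefix Ontology prefix, e.g. `"UNIMOD"`.
#' @param label Term label, matched case-insensitively.
#' @return The accession, or `NULL` when absent.
#' @export
find_by_label <- function(store, prefix, label) {
  stopifnot(inherits(store, "cv_store"))
  key <- paste(tolower(prefix), tolower(label), sep = "\x1f")
  if (!key %in% names(store$acc_by_key)) return(NULL)
  unname(store$acc_by_key[[key]])
}
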