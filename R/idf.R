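# IDF study-description files.
#
# An IDF file is a series of key/value lines: the first tab-delimited cell of
# each line is the key ("Investigation Title", "Person Last Name", ...), the
# remaining cells are its values. Most keys accept several values; person
# keys stay column-aligned so that the i-th value of every person key
# describes the same person.

#' Construct an IDF document
#'
#' @param entries A list of `list(key =, values =)` pairs, or a tibble with
#'   columns `key` (character) and `values` (list of character vectors).
#' @param sdrf_reference Optional SDRF file name referenced by the document.
#' @return An object of class `idf_document`.
#' @export
idf_document <- function(entries = list(), sdrf_reference = NULL) {
  if (is.data.frame(entries)) {
    entries <- lapply(seq_len(nrow(entries)), function(i) {
      list(key = entries$key[i], values = entries$values[[i]])
    })
  }
  keys <- vapply(entries, function(e) e$key, character(1))
  dup <- keys[duplicated(tolower(keys))]
  if (length(dup)) {
    sdrf_parse_error("duplicate IDF key(s): %s", paste(dup, collapse = ", "))
  }
  structure(list(entries = entries, sdrf_reference = sdrf_reference),
            class = "idf_document")
}

#' @export
print.idf_document <- function(x, ...) {
  cat(sprintf("<idf_document> %d entr%s\n", length(x$entries),
              if (length(x$entries) == 1) "y" else "ies"))
  invisible(x)
}

idf_keys <- function(doc) {
  vapply(doc$entries, function(e) e$key, character(1))
}

#' Look up an IDF entry's values by key (case-insensitive)
#' @param doc An [idf_document()].
#' @param key Key text.
#' @return Character vector of values (empty when the key is absent).
#' @export
idf_value <- function(doc, key) {
  hit <- which(tolower(idf_keys(doc)) == tolower(key))
  if (!length(hit)) return(character(0))
  doc$entries[[hit[1]]]$values
}

#' Read an IDF file
#'
#' The first cell of each tab-delimited line is the key, the remaining cells
#' its values (trailing empty cells dropped). Empty lines and lines starting
#' with `#` are ignored. Keys are unique case-insensitively; a `SDRF File`
#' key additionally populates the document's `sdrf_reference`.
#'
#' @param file Path or connection.
#' @return An [idf_document()].
#' @export
read_idf <- function(file) {
  lines <- read_utf8_lines(file)
  entries <- list()
  seen <- character(0)
  sdrf_reference <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    cells <- split_tsv_line(line)
    key <- trimws(cells[1])
    if (!nzchar(key)) {
      sdrf_parse_error("line %d: IDF line has an empty key", i)
    }
    if (tolower(key) %in% seen) {
      sdrf_parse_error("duplicate IDF key '%s' (line %d)", key, i)
    }
    seen <- c(seen, tolower(key))
    values <- cells[-1]
    while (length(values) && !nzchar(values[length(values)])) {
      values <- values[-length(values)]
    }
    if (tolower(key) == "sdrf file" && length(values)) {
      sdrf_reference <- values[1]
    }
    entries <- c(entries, list(list(key = key, values = values)))
  }
  idf_document(entries, sdrf_reference)
}

#' Write an IDF file
#'
#' One tab-delimited line per entry, in stored order; reading the output back
#' reproduces the document.
#'
#' @param doc An [idf_document()].
#' @param file Path or connection.
#' @return `doc`, invisibly.
#' @export
write_idf <- function(doc, file) {
  stopifnot(inherits(doc, "idf_document"))
  lines <- vapply(doc$entries, function(e) {
    fields <- c(e$key, e$values)
    if (any(grepl("[\t\n\r]", fields))) {
      sdrf_parse_error("IDF entry '%s' embeds a tab or newline", e$key)
    }
    paste(fields, collapse = "\t")
  }, character(1))
  write_utf8_lines(lines, file)
  invisible(doc)
}

#' Construct a dataset-description record
#'
#' A neutral study-description record carrying the fields repositories
#' collect at submission time (title, free-text description, submitters,
#' instruments, software, publications, keywords). [idf_from_description()]
#' turns it into an IDF document.
#'
#' @param title Dataset title; required, non-empty.
#' @param description Free-text experiment description.
#' @param submitters Data frame with columns `name`, `affiliation`, `email`
#'   (or `NULL`).
#' @param instruments List of [ontology_annotation()] objects or character
#'   labels.
#' @param software Character vector of analysis software names.
#' @param publications Character vector of publication titles.
#' @param keywords Character vector of keywords.
#' @return An object of class `dataset_description`.
#' @export
dataset_description <- function(title, description = "", submitters = NULL,
                                instruments = list(), software = character(0),
                                publications = character(0),
                                keywords = character(0)) {
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title))) {
    sdrf_parse_error("dataset title must be non-empty")
  }
  if (!is.null(submitters)) {
    stopifnot(is.data.frame(submitters),
              all(c("name", "affiliation", "email") %in% names(submitters)))
  }
  structure(
    list(title = title, description = description, submitters = submitters,
         instruments = instruments, software = as.character(software),
         publications = as.character(publications),
         keywords = as.character(keywords)),
    class = "dataset_description"
  )
}

split_person_name <- function(name) {
  name <- trimws(name)
  if (!grepl("[[:space:]]", name)) {
    return(c(first = "", last = name))
  }
  c(first = trimws(sub("[[:space:]]+[^[:space:]]+$", "", name)),
    last = sub("^.*[[:space:]]", "", name))
}

#' Build an IDF document from a dataset description
#'
#' Deterministic mapping: title to `Investigation Title`, description to
#' `Experiment Description`, submitter names split on the last whitespace
#' into `Person Last Name` / `Person First Name`, then `Person Affiliation`,
#' `Person Email`, `Publication Title` and `Comment[Keywords]`, in that
#' order. Person keys are emitted in parallel so values stay column-aligned
#' per person. Instruments and software follow as `Comment[Instrument]` and
#' `Software` so the record round-trips losslessly.
#'
#' @param desc A [dataset_description()].
#' @return An [idf_document()].
#' @export
idf_from_description <- function(desc) {
  stopifnot(inherits(desc, "dataset_description"))
  if (!nzchar(trimws(desc$title))) {
    sdrf_parse_error("dataset title must be non-empty")
  }
  entries <- list(list(key = "Investigation Title", values = desc$title))
  add <- function(key, values) {
    values <- as.character(values)
    if (length(values) && any(nzchar(values))) {
      entries[[length(entries) + 1L]] <<- list(key = key, values = values)
    }
  }
  add("Experiment Description", desc$description)
  if (!is.null(desc$submitters) && nrow(desc$submitters)) {
    parts <- t(vapply(desc$submitters$name, split_person_name, character(2)))
    add("Person Last Name", parts[, "last"])
    add("Person First Name", parts[, "first"])
    add("Person Affiliation", desc$submitters$affiliation)
    add("Person Email", desc$submitters$email)
  }
  add("Publication Title", desc$publications)
  add("Comment[Keywords]", desc$keywords)
  add("Comment[Instrument]", vapply(desc$instruments, function(x) {
    if (inherits(x, "ontology_annotation")) x$label else as.character(x)
  }, character(1)))
  add("Software", desc$software)
  idf_document(entries)
}

#' Recover a dataset description from an IDF document
#'
#' Inverse of [idf_from_description()] over the mapped keys; title and
#' description are recovered verbatim.
#'
#' @param doc An [idf_document()].
#' @return A [dataset_description()].
#' @export
description_from_idf <- function(doc) {
  stopifnot(inherits(doc, "idf_document"))
  title <- idf_value(doc, "Investigation Title")
  if (!length(title)) {
    sdrf_parse_error("IDF document has no 'Investigation Title'")
  }
  lasts <- idf_value(doc, "Person Last Name")
  firsts <- idf_value(doc, "Person First Name")
  affs <- idf_value(doc, "Person Affiliation")
  emails <- idf_value(doc, "Person Email")
  submitters <- NULL
  if (length(lasts)) {
    n <- length(lasts)
    pad <- function(x) c(x, rep("", n))[seq_len(n)]
    firsts <- pad(firsts)
    names <- trimws(paste(firsts, lasts))
    submitters <- data.frame(name = names, affiliation = pad(affs),
                             email = pad(emails), stringsAsFactors = FALSE)
  }
  description <- idf_value(doc, "Experiment Description")
  dataset_description(
    title = title[1],
    description = if (length(description)) description[1] else "",
    submitters = submitters,
    instruments = as.list(idf_value(doc, "Comment[Instrument]")),
    software = idf_value(doc, "Software"),
    publications = idf_value(doc, "Publication Title"),
    keywords = idf_value(doc, "Comment[Keywords]")
  )
}
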