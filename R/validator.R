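# Structural, template and vocabulary validation of SDRF tables.
#
# Every problem is a graded finding (ERROR / WARNING / INFO) with a stable
# rule code and, where applicable, 1-based data-row and canonical-column
# coordinates. A table is valid when it has zero ERROR findings.
#
# Structural rule registry:
#   S1  ERROR   exactly one source name and one assay name column
#   S2  ERROR   comment[data file] present
#   S3  ERROR   mandatory characteristics present (organism, organism part,
#               biological replicate)
#   S4  ERROR   mandatory comments present (fraction identifier, technical
#               replicate, data file)
#   S5  ERROR   no empty/missing cell in a required column
#   S6  ERROR   fraction identifiers are positive integers
#   S7  ERROR   rows sharing a source name agree on every characteristic
#   S8  ERROR   rows sharing a data file agree on fraction identifier,
#               technical replicate and instrument
#   S9  ERROR   one (data file, label) pair maps to one source name
#   S10 WARNING recommended comments missing (instrument, cleavage agent,
#               fragment/precursor mass tolerance, modification parameters)
#   S11 WARNING label value outside the bundled label list
#   S12 WARNING exact duplicate rows
#   S13 INFO    factor value column with a single distinct value
#   S14 ERROR   comment[label] column missing ("label free sample" marks
#               unlabeled runs)
# Template rules carry template-local codes (H1..H4, C1); vocabulary rules
# are V1 (unknown accession), V2 (label/accession mismatch), V3 (unknown
# key in a key/value cell, info).

SEVERITIES <- c("ERROR", "WARNING", "INFO")

REQUIRED_CHARACTERISTICS <- c("organism", "organism part",
                              "biological replicate")
REQUIRED_COMMENTS <- c("fraction identifier", "technical replicate",
                       "data file")
RECOMMENDED_COMMENTS <- c("instrument", "cleavage agent",
                          "fragment mass tolerance",
                          "precursor mass tolerance",
                          "modification parameters")

tmt_channels <- function(n) {
  switch(as.character(n),
    "6" = paste0("TMT", 126:131),
    "10" = c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
             "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131"),
    "11" = c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
             "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131",
             "TMT131C"),
    "16" = c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
             "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131N",
             "TMT131C", "TMT132N", "TMT132C", "TMT133N", "TMT133C",
             "TMT134N"),
    stop(sprintf("unsupported TMT plex size %s", n), call. = FALSE)
  )
}

#' Label values known to the validator
#'
#' The bundled list of labeling-channel names: TMT 6/10/11-plex channels,
#' TMTpro 16-plex channels, SILAC light/medium/heavy and the
#' `"label free sample"` sentinel for unlabeled runs.
#'
#' @return Character vector of label names.
#' @export
known_labels <- function() {
  unique(c(tmt_channels(6), tmt_channels(10), tmt_channels(11),
           tmt_channels(16),
           "SILAC light", "SILAC medium", "SILAC heavy",
           "label free sample"))
}

finding <- function(severity, rule_id, message, row = NA_integer_,
                    column = NA_character_) {
  tibble::tibble(severity = severity, rule_id = rule_id, message = message,
                 row = as.integer(row), column = column)
}

no_findings <- function() {
  finding(character(0), character(0), character(0), integer(0), character(0))
}

bind_findings <- function(...) {
  do.call(rbind, Filter(Negate(is.null), list(...)))
}

# group index helper: per distinct key, the data-row indices
rows_by_value <- function(values) {
  split(seq_along(values), factor(values, levels = unique(values)))
}

# within-group agreement check shared by S7/S8
agreement_findings <- function(table, group_col_idx, check_idx, rule_id,
                               what) {
  out <- no_findings()
  if (is.na(group_col_idx) || !length(check_idx) || !nrow(table$cells)) {
    return(out)
  }
  groups <- rows_by_value(table$cells[, group_col_idx])
  for (nm in names(groups)) {
    rows <- groups[[nm]]
    if (length(rows) < 2L) next
    for (ci in check_idx) {
      vals <- table$cells[rows, ci]
      if (length(unique(vals)) > 1L) {
        dev <- rows[which(vals != vals[1])[1]]
        out <- bind_findings(out, finding(
          "ERROR", rule_id,
          sprintf("rows sharing %s '%s' disagree on '%s'", what, nm,
                  format_column_header(table$columns[[ci]])),
          row = dev, column = format_column_header(table$columns[[ci]])))
      }
    }
  }
  out
}

#' Structural validation of an SDRF table
#'
#' Applies the structural rule registry (S1-S14): identifier columns,
#' mandatory and recommended properties, fraction-identifier syntax, and the
#' row semantics tying sample properties to source names and file properties
#' to data files. All problems are returned as findings, never thrown.
#'
#' @param table An [sdrf_table()].
#' @return A findings tibble (`severity`, `rule_id`, `message`, `row`,
#'   `column`).
#' @export
validate_structure <- function(table) {
  stopifnot(inherits(table, "sdrf_table"))
  out <- no_findings()
  n <- nrow(table$cells)

  # S1 identifier columns
  n_src <- length(col_which(table, "SOURCE_NAME"))
  n_assay <- length(col_which(table, "ASSAY_NAME"))
  if (n_src != 1L) {
    out <- bind_findings(out, finding(
      "ERROR", "S1",
      sprintf("expected exactly one 'source name' column, found %d", n_src)))
  }
  if (n_assay != 1L) {
    out <- bind_findings(out, finding(
      "ERROR", "S1",
      sprintf("expected exactly one 'assay name' column, found %d", n_assay)))
  }

  # S2 data file column
  file_idx <- col_one(table, "COMMENT", "data file")
  if (is.na(file_idx)) {
    out <- bind_findings(out, finding(
      "ERROR", "S2", "missing 'comment[data file]' column",
      column = "comment[data file]"))
  }

  # S3 mandatory characteristics
  for (attr in REQUIRED_CHARACTERISTICS) {
    if (is.na(col_one(table, "CHARACTERISTICS", attr))) {
      out <- bind_findings(out, finding(
        "ERROR", "S3",
        sprintf("missing mandatory 'characteristics[%s]' column", attr),
        column = sprintf("characteristics[%s]", attr)))
    }
  }

  # S4 mandatory comments
  for (attr in REQUIRED_COMMENTS) {
    if (is.na(col_one(table, "COMMENT", attr))) {
      out <- bind_findings(out, finding(
        "ERROR", "S4",
        sprintf("missing mandatory 'comment[%s]' column", attr),
        column = sprintf("comment[%s]", attr)))
    }
  }

  # S5 no empty cell in required columns
  required_idx <- c(
    col_which(table, "SOURCE_NAME"), col_which(table, "ASSAY_NAME"),
    unlist(lapply(REQUIRED_CHARACTERISTICS, function(a) {
      col_which(table, "CHARACTERISTICS", a)
    })),
    unlist(lapply(c(REQUIRED_COMMENTS, "label"), function(a) {
      col_which(table, "COMMENT", a)
    }))
  )
  for (ci in required_idx) {
    empties <- which(is_missing_cell(table$cells[, ci]))
    for (r in empties) {
      out <- bind_findings(out, finding(
        "ERROR", "S5",
        sprintf("empty value in required column '%s'",
                format_column_header(table$columns[[ci]])),
        row = r, column = format_column_header(table$columns[[ci]])))
    }
  }

  # S6 fraction identifiers are positive integers
  frac_idx <- col_one(table, "COMMENT", "fraction identifier")
  if (!is.na(frac_idx) && n) {
    bad <- which(!grepl("^[0-9]+$", table$cells[, frac_idx]) |
                   suppressWarnings(as.numeric(table$cells[, frac_idx])) < 1)
    for (r in bad) {
      out <- bind_findings(out, finding(
        "ERROR", "S6",
        sprintf("fraction identifier '%s' is not a positive integer",
                table$cells[r, frac_idx]),
        row = r, column = "comment[fraction identifier]"))
    }
  }

  # S7 sample properties agree across the rows of one source name
  out <- bind_findings(out, agreement_findings(
    table, col_one(table, "SOURCE_NAME"),
    col_which(table, "CHARACTERISTICS"), "S7", "source name"))

  # S8 file properties agree across the rows of one data file
  s8_idx <- c(col_one(table, "COMMENT", "fraction identifier"),
              col_one(table, "COMMENT", "technical replicate"),
              col_one(table, "COMMENT", "instrument"))
  out <- bind_findings(out, agreement_findings(
    table, file_idx, s8_idx[!is.na(s8_idx)], "S8", "data file"))

  # S9 (data file, label) identifies one source name
  label_idx <- col_one(table, "COMMENT", "label")
  src_idx <- col_one(table, "SOURCE_NAME")
  if (!is.na(file_idx) && !is.na(src_idx) && n) {
    labels <- if (is.na(label_idx)) rep("label free sample", n)
              else table$cells[, label_idx]
    pair <- paste(table$cells[, file_idx], labels, sep = "\x1f")
    for (rows in rows_by_value(pair)) {
      srcs <- unique(table$cells[rows, src_idx])
      if (length(srcs) > 1L) {
        out <- bind_findings(out, finding(
          "ERROR", "S9",
          sprintf("data file '%s' label '%s' maps to %d source names (%s)",
                  table$cells[rows[1], file_idx], labels[rows[1]],
                  length(srcs), paste(srcs, collapse = ", ")),
          row = rows[2], column = "comment[data file]"))
      }
    }
  }

  # S10 recommended search-parameter comments
  for (attr in RECOMMENDED_COMMENTS) {
    if (!length(col_which(table, "COMMENT", attr))) {
      out <- bind_findings(out, finding(
        "WARNING", "S10",
        sprintf("recommended 'comment[%s]' column is missing", attr),
        column = sprintf("comment[%s]", attr)))
    }
  }

  # S11 label values from the bundled list
  if (!is.na(label_idx) && n) {
    unknown <- which(!table$cells[, label_idx] %in% known_labels() &
                       !is_missing_cell(table$cells[, label_idx]))
    for (v in unique(table$cells[unknown, label_idx])) {
      out <- bind_findings(out, finding(
        "WARNING", "S11",
        sprintf("label '%s' is not in the bundled label list", v),
        row = unknown[table$cells[unknown, label_idx] == v][1],
        column = "comment[label]"))
    }
  }

  # S12 exact duplicate rows
  if (n > 1L) {
    whole <- apply(table$cells, 1L, paste, collapse = "\x1f")
    for (r in which(duplicated(whole))) {
      out <- bind_findings(out, finding(
        "WARNING", "S12",
        sprintf("row %d duplicates an earlier row exactly", r), row = r))
    }
  }

  # S13 constant factor value columns
  for (ci in col_which(table, "FACTOR_VALUE")) {
    if (n && length(unique(table$cells[, ci])) == 1L) {
      out <- bind_findings(out, finding(
        "INFO", "S13",
        sprintf("factor value column '%s' has a single distinct value",
                format_column_header(table$columns[[ci]])),
        column = format_column_header(table$columns[[ci]])))
    }
  }

  # S14 label column required (label-free uses the sentinel value)
  if (is.na(label_idx)) {
    out <- bind_findings(out, finding(
      "ERROR", "S14",
      "missing 'comment[label]' column (use 'label free sample' for unlabeled runs)",
      column = "comment[label]"))
  }

  out
}

#' Load a validation template schema
#'
#' Templates are structured text files: a `name` line plus `rule` lines
#' (`rule <id> <kind> <severity> <column> [<datum>]`). Bundled templates:
#' `default`, `human`, `cell-line`. A path to a user-supplied template file
#' is also accepted, so repository-specific policies need no code changes.
#'
#' @param name Template name or path to a template file.
#' @return An object of class `template_schema`.
#' @export
load_template <- function(name = "default") {
  dir <- system.file("extdata", "templates", package = "sdrftab")
  available <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
  path <- if (file.exists(name)) name else file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(path)) {
    stop(sprintf("unknown template '%s'; available templates: %s",
                 name, paste(available, collapse = ", ")), call. = FALSE)
  }
  lines <- read_utf8_lines(path)
  template_name <- NULL
  rules <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    cells <- split_tsv_line(line)
    if (cells[1] == "name") {
      template_name <- cells[2]
    } else if (cells[1] == "rule") {
      if (length(cells) < 5L) {
        sdrf_parse_error("%s, line %d: malformed template rule", path, i)
      }
      rules <- c(rules, list(list(
        id = cells[2], kind = cells[3], severity = cells[4],
        column = cells[5], datum = if (length(cells) >= 6L) cells[6] else NA)))
    } else {
      sdrf_parse_error("%s, line %d: unknown template directive '%s'",
                       path, i, cells[1])
    }
  }
  if (is.null(template_name)) {
    sdrf_parse_error("template file %s has no 'name' line", path)
  }
  structure(list(name = template_name, rules = rules), class = "template_schema")
}

#' Template-specific validation
#'
#' Applies the rules of one experiment-type template on top of the structural
#' rules: required columns (e.g. `characteristics[disease]` for human
#' datasets), fixed cell values (organism must read `Homo sapiens`) and
#' expected values (at least one control sample labeled `normal`,
#' case-insensitive).
#'
#' @param table An [sdrf_table()].
#' @param template A `template_schema` from [load_template()], or a template
#'   name.
#' @param explicit Whether the template was requested explicitly; resolves
#'   `ERROR_IF_EXPLICIT` severities (default `TRUE`).
#' @return A findings tibble.
#' @export
validate_template <- function(table, template = load_template("default"),
                              explicit = TRUE) {
  stopifnot(inherits(table, "sdrf_table"))
  if (is.character(template)) template <- load_template(template)
  stopifnot(inherits(template, "template_schema"))
  out <- no_findings()
  for (rule in template$rules) {
    severity <- rule$severity
    if (severity == "ERROR_IF_EXPLICIT") {
      severity <- if (explicit) "ERROR" else "WARNING"
    }
    key <- parse_column_header(rule$column)
    idx <- col_which(table, key$category, key$attribute)
    if (rule$kind == "require") {
      if (!length(idx)) {
        out <- bind_findings(out, finding(
          severity, rule$id,
          sprintf("template '%s' requires column '%s'", template$name,
                  rule$column),
          column = rule$column))
      }
    } else if (rule$kind == "value_equals") {
      if (length(idx)) {
        bad <- which(table$cells[, idx[1]] != rule$datum)
        for (r in bad) {
          out <- bind_findings(out, finding(
            severity, rule$id,
            sprintf("template '%s' expects '%s' to be '%s', found '%s'",
                    template$name, rule$column, rule$datum,
                    table$cells[r, idx[1]]),
            row = r, column = rule$column))
        }
      }
    } else if (rule$kind == "expect_value") {
      if (length(idx) && nrow(table$cells) &&
          !any(tolower(table$cells[, idx[1]]) == tolower(rule$datum))) {
        out <- bind_findings(out, finding(
          severity, rule$id,
          sprintf("template '%s': no '%s' cell has the value '%s'",
                  template$name, rule$column, rule$datum),
          column = rule$column))
      }
    } else {
      stop(sprintf("unknown template rule kind '%s'", rule$kind),
           call. = FALSE)
    }
  }
  out
}

#' Controlled-vocabulary validation
#'
#' Inspects characteristics and comment cells written in key/value syntax.
#' A cell carrying an `AC` accession is checked against the store: unknown
#' accessions and label/accession mismatches (the stored label differs
#' case-insensitively from the cell's `NT`) are warnings; keys outside the
#' understood set are reported at info level. Free-text cells are always
#' allowed and produce no finding.
#'
#' @param table An [sdrf_table()].
#' @param store A `cv_store`, by default the bundled snapshots.
#' @return A findings tibble.
#' @export
validate_terms <- function(table, store = default_cv_store()) {
  stopifnot(inherits(table, "sdrf_table"), inherits(store, "cv_store"))
  out <- no_findings()
  idx <- c(col_which(table, "CHARACTERISTICS"), col_which(table, "COMMENT"))
  for (ci in idx) {
    colname <- format_column_header(table$columns[[ci]])
    for (r in seq_len(nrow(table$cells))) {
      cell <- table$cells[r, ci]
      if (!grepl("=", cell, fixed = TRUE)) next
      kv <- tryCatch(parse_key_value_cell(cell),
                     sdrf_parse_error = function(e) NULL)
      if (is.null(kv)) next
      unknown <- setdiff(names(kv), KNOWN_KV_KEYS)
      if (length(unknown)) {
        out <- bind_findings(out, finding(
          "INFO", "V3",
          sprintf("key/value cell carries unrecognized key(s): %s",
                  paste(unknown, collapse = ", ")),
          row = r, column = colname))
      }
      if (!"AC" %in% names(kv)) next
      hit <- lookup_accession(store, kv[["AC"]])
      if (is.null(hit)) {
        out <- bind_findings(out, finding(
          "WARNING", "V1",
          sprintf("accession '%s' not found in the vocabulary store",
                  kv[["AC"]]),
          row = r, column = colname))
      } else if ("NT" %in% names(kv) &&
                 tolower(hit$label) != tolower(kv[["NT"]])) {
        out <- bind_findings(out, finding(
          "WARNING", "V2",
          sprintf("accession '%s' is '%s' in the store but the cell names it '%s'",
                  kv[["AC"]], hit$label, kv[["NT"]]),
          row = r, column = colname))
      }
    }
  }
  out
}

#' Full validation of an SDRF table
#'
#' Runs the structural, template and vocabulary rule families and aggregates
#' their findings into a report with per-severity counts. Findings are
#' ordered deterministically by rule id, then row, then column, so identical
#' inputs yield identical reports.
#'
#' @param table An [sdrf_table()].
#' @param template A `template_schema` or template name (default `"default"`).
#' @param store A `cv_store` (default: bundled snapshots).
#' @param explicit Passed to [validate_template()].
#' @return An object of class `validation_report` with fields `findings`
#'   (tibble), `counts` (named integer vector over ERROR/WARNING/INFO) and
#'   `valid` (`TRUE` iff no ERROR findings).
#' @export
validate <- function(table, template = load_template("default"),
                     store = default_cv_store(), explicit = TRUE) {
  findings <- bind_findings(
    validate_structure(table),
    validate_template(table, template, explicit = explicit),
    validate_terms(table, store)
  )
  ord <- order(findings$rule_id,
               ifelse(is.na(findings$row), .Machine$integer.max, findings$row),
               ifelse(is.na(findings$column), "\xff", findings$column),
               method = "radix")
  findings <- findings[ord, ]
  counts <- vapply(SEVERITIES, function(s) sum(findings$severity == s),
                   integer(1))
  structure(list(findings = findings, counts = counts,
                 valid = counts[["ERROR"]] == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a validation report as human-readable text
#' @param report A `validation_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  head <- sprintf("%s: %d error(s), %d warning(s), %d info",
                  if (report$valid) "VALID" else "INVALID",
                  report$counts[["ERROR"]], report$counts[["WARNING"]],
                  report$counts[["INFO"]])
  if (!nrow(report$findings)) return(head)
  body <- vapply(seq_len(nrow(report$findings)), function(i) {
    f <- report$findings[i, ]
    loc <- c(if (!is.na(f$row)) sprintf("row %d", f$row),
             if (!is.na(f$column)) sprintf("column '%s'", f$column))
    sprintf("  %-7s [%s]%s %s", f$severity, f$rule_id,
            if (length(loc)) paste0(" (", paste(loc, collapse = ", "), ")")
            else "",
            f$message)
  }, character(1))
  c(head, body)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::toJSON(
    list(valid = report$valid,
         counts = as.list(report$counts),
         findings = report$findings),
    auto_unbox = TRUE, na = "null", pretty = TRUE)
}
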