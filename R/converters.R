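# Derive downstream analysis inputs from a validated SDRF table.
#
# Two canonical outputs: a per-file search-parameter record (instrument,
# cleavage agent, tolerances, modifications partitioned into fixed /
# variable, with annotated modifications echoed separately) and a flat
# per-row annotation table (run, fraction, label, replicates, condition)
# for quantification workflows. Both converters are pure.

# ensure the table has no structural errors before converting
assert_convertible <- function(table) {
  findings <- validate_structure(table)
  errors <- findings[findings$severity == "ERROR", ]
  if (nrow(errors)) {
    stop(sprintf(
      "table has %d structural validation error(s); first: [%s] %s",
      nrow(errors), errors$rule_id[1], errors$message[1]), call. = FALSE)
  }
  invisible(table)
}

# the single value a column takes over a row group; conflict -> error
uniform_cell <- function(table, rows, col_idx, file_name) {
  vals <- table$cells[rows, col_idx]
  keep <- vals[!is_missing_cell(vals)]
  if (!length(keep)) return(NULL)
  if (length(unique(keep)) > 1L) {
    stop(sprintf("conflicting values for data file '%s' in column '%s': %s",
                 file_name, format_column_header(table$columns[[col_idx]]),
                 paste(unique(keep), collapse = " / ")), call. = FALSE)
  }
  keep[1]
}

parse_instrument_cell <- function(cell) {
  if (grepl("=", cell, fixed = TRUE)) {
    kv <- parse_key_value_cell(cell)
    ontology_annotation(
      label = if ("NT" %in% names(kv)) kv[["NT"]] else kv[["AC"]],
      accession = if ("AC" %in% names(kv)) kv[["AC"]] else NULL)
  } else {
    ontology_annotation(label = cell)
  }
}

label_scheme_of <- function(labels) {
  labels <- unique(labels)
  if (all(labels == "label free sample")) return("label free")
  if (any(startsWith(labels, "TMT"))) return("tmt")
  if (any(startsWith(labels, "SILAC"))) return("silac")
  "other"
}

#' Extract per-file search parameters from an SDRF table
#'
#' One record per distinct data file (first-appearance order), with values
#' parsed through the key/value micro-syntax: instrument, cleavage agent,
#' precursor and fragment mass tolerances, and all modification columns,
#' partitioned into fixed and variable search modifications (annotated
#' modifications are echoed separately, not searched). Columns absent from
#' the table yield absent fields. A file whose rows disagree on one of these
#' values is an error naming the file and column.
#'
#' @param table An [sdrf_table()] with no structural validation errors.
#' @return A list of `search_params` objects.
#' @export
extract_search_params <- function(table) {
  assert_convertible(table)
  file_idx <- col_one(table, "COMMENT", "data file")
  label_idx <- col_one(table, "COMMENT", "label")
  instr_idx <- col_one(table, "COMMENT", "instrument")
  enz_idx <- col_one(table, "COMMENT", "cleavage agent")
  prec_idx <- col_one(table, "COMMENT", "precursor mass tolerance")
  frag_idx <- col_one(table, "COMMENT", "fragment mass tolerance")
  mod_idx <- col_which(table, "COMMENT", "modification parameters")

  groups <- rows_by_value(table$cells[, file_idx])
  lapply(names(groups), function(file_name) {
    rows <- groups[[file_name]]
    grab <- function(idx) {
      if (is.na(idx)) NULL else uniform_cell(table, rows, idx, file_name)
    }
    wrap <- function(cell, parser, idx) {
      if (is.null(cell)) return(NULL)
      tryCatch(parser(cell), sdrf_parse_error = function(e) {
        stop(sprintf("row %d, column '%s': %s", rows[1],
                     format_column_header(table$columns[[idx]]),
                     conditionMessage(e)), call. = FALSE)
      })
    }
    mods <- list()
    for (mi in mod_idx) {
      cell <- uniform_cell(table, rows, mi, file_name)
      if (!is.null(cell)) {
        mods <- c(mods, list(wrap(cell, parse_modification, mi)))
      }
    }
    types <- vapply(mods, function(m) m$mod_type, character(1))
    labels <- if (is.na(label_idx)) "label free sample"
              else table$cells[rows, label_idx]
    structure(
      list(
        data_file = file_name,
        instrument = wrap(grab(instr_idx), parse_instrument_cell, instr_idx),
        enzyme = wrap(grab(enz_idx), parse_enzyme, enz_idx),
        precursor_tolerance = wrap(grab(prec_idx), parse_tolerance, prec_idx),
        fragment_tolerance = wrap(grab(frag_idx), parse_tolerance, frag_idx),
        fixed_modifications = mods[types == "FIXED"],
        variable_modifications = mods[types == "VARIABLE"],
        annotated_modifications = mods[types == "ANNOTATED"],
        label_scheme = label_scheme_of(labels)
      ),
      class = "search_params"
    )
  })
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf("<search_params> %s (%s)\n", x$data_file, x$label_scheme))
  invisible(x)
}

search_params_as_list <- function(p) {
  mod_list <- function(mods) {
    lapply(mods, function(m) {
      Filter(Negate(is.null), list(
        name = m$name, accession = m$accession, type = m$mod_type,
        target_amino_acids = as.list(m$target_amino_acids),
        position = m$position, monoisotopic_mass = m$monoisotopic_mass,
        chemical_formula = m$chemical_formula))
    })
  }
  out <- list(data_file = p$data_file)
  if (!is.null(p$instrument)) {
    out$instrument <- Filter(Negate(is.null),
                             list(label = p$instrument$label,
                                  accession = p$instrument$accession))
  }
  if (!is.null(p$enzyme)) {
    out$cleavage_agent <- Filter(Negate(is.null),
                                 list(name = p$enzyme$name,
                                      accession = p$enzyme$accession,
                                      cleavage_site = p$enzyme$cleavage_site))
  }
  if (!is.null(p$precursor_tolerance)) {
    out$precursor_tolerance <- format_tolerance(p$precursor_tolerance)
  }
  if (!is.null(p$fragment_tolerance)) {
    out$fragment_tolerance <- format_tolerance(p$fragment_tolerance)
  }
  out$fixed_modifications <- mod_list(p$fixed_modifications)
  out$variable_modifications <- mod_list(p$variable_modifications)
  out$annotated_modifications <- mod_list(p$annotated_modifications)
  out$label_scheme <- p$label_scheme
  out
}

#' Write search-parameter documents
#'
#' One structured YAML document per data file, named
#' `<file stem>.params.yml`, with stable key order.
#'
#' @param params List of `search_params` from [extract_search_params()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_search_params <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(params, function(p) {
    stem <- sub("\\.[^.]*$", "", p$data_file)
    path <- file.path(dir, paste0(stem, ".params.yml"))
    yaml::write_yaml(search_params_as_list(p), path)
    path
  }, character(1))
  invisible(paths)
}

#' Flatten an SDRF table to a per-row annotation table
#'
#' One annotation row per SDRF data row, in order: `run` (data file name
#' with only its final extension stripped), `fraction` (integer fraction
#' identifier), `label`, `bio_replicate`, `tech_replicate`, and `condition`
#' (all factor value cells of the row joined with `_` in column order). The
#' variables under study must be declared: a table with no factor value
#' column is an error.
#'
#' @param table An [sdrf_table()] with no structural validation errors.
#' @return A tibble with columns
#'   `run,fraction,label,bio_replicate,tech_replicate,condition`.
#' @export
to_annotation_table <- function(table) {
  assert_convertible(table)
  factor_idx <- col_which(table, "FACTOR_VALUE")
  if (!length(factor_idx)) {
    stop("table has no 'factor value[...]' column: the variables under study must be specified",
         call. = FALSE)
  }
  n <- nrow(table$cells)
  file_idx <- col_one(table, "COMMENT", "data file")
  frac_idx <- col_one(table, "COMMENT", "fraction identifier")
  label_idx <- col_one(table, "COMMENT", "label")
  bio_idx <- col_one(table, "CHARACTERISTICS", "biological replicate")
  tech_idx <- col_one(table, "COMMENT", "technical replicate")
  condition <- if (n) {
    apply(table$cells[, factor_idx, drop = FALSE], 1L, paste, collapse = "_")
  } else {
    character(0)
  }
  tibble::tibble(
    run = sub("\\.[^.]*$", "", table$cells[, file_idx]),
    fraction = as.integer(table$cells[, frac_idx]),
    label = if (is.na(label_idx)) rep("label free sample", n)
            else table$cells[, label_idx],
    bio_replicate = table$cells[, bio_idx],
    tech_replicate = table$cells[, tech_idx],
    condition = condition
  )
}

#' Write an annotation table as CSV
#'
#' Header `run,fraction,label,bio_replicate,tech_replicate,condition`;
#' values are quoted only when needed.
#'
#' @param annotation Tibble from [to_annotation_table()].
#' @param file Output path.
#' @return `annotation`, invisibly.
#' @export
write_annotation_csv <- function(annotation, file) {
  utils::write.csv(annotation, file, row.names = FALSE, quote = FALSE)
  invisible(annotation)
}
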