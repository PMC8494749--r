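# Key/value micro-syntax used inside SDRF cells.
#
# Complex cell values (modifications, cleavage agents, instruments) are
# encoded as semicolon-separated key/value pairs, e.g.
# "AC=UNIMOD:35;NT=Oxidation;MT=Variable;TA=M". A bare cell with no "=" is
# shorthand for a name-only value (reserved key NT).

# accession shaped like PREFIX:ID
ACCESSION_RE <- "^[A-Za-z]+[A-Za-z0-9_]*:[A-Za-z0-9_.]+$"

#' Ontology term annotation
#'
#' A label with an optional `PREFIX:ID` accession (e.g. `UNIMOD:35`) and an
#' optional ontology prefix. SDRF properties may be annotated with ontology
#' terms; free text is also allowed.
#'
#' @param label Human-readable term label.
#' @param accession Optional accession of the form `PREFIX:ID`.
#' @param source Optional ontology prefix; defaults to the accession prefix.
#' @return An object of class `ontology_annotation`.
#' @export
#' @examples
#' ontology_annotation("Oxidation", "UNIMOD:35")
ontology_annotation <- function(label, accession = NULL, source = NULL) {
  label <- as.character(label)
  if (!is.null(accession)) {
    accession <- as.character(accession)
    if (!grepl(ACCESSION_RE, accession)) {
      sdrf_parse_error("malformed accession '%s' (expected PREFIX:ID)",
                       accession)
    }
    if (is.null(source)) source <- sub(":.*$", "", accession)
  }
  structure(list(label = label, accession = accession, source = source),
            class = "ontology_annotation")
}

#' Parse a key/value SDRF cell
#'
#' Splits the cell on `;`, each item on its first `=`. Keys are upper-cased
#' and whitespace-trimmed, values are trimmed, and pair order is preserved.
#' A cell without any `=` is the bare-name shorthand and yields a single `NT`
#' entry.
#'
#' @param cell Non-empty cell text.
#' @return A named character vector in cell order.
#' @export
#' @examples
#' parse_key_value_cell("AC=UNIMOD:35;NT=Oxidation;MT=Variable;TA=M")
#' parse_key_value_cell("Oxidation")
parse_key_value_cell <- function(cell) {
  if (!is.character(cell) || length(cell) != 1L || is.na(cell) ||
      !nzchar(trimws(cell))) {
    sdrf_parse_error("key/value cell must be a non-empty string")
  }
  if (!grepl("=", cell, fixed = TRUE)) {
    return(c(NT = trimws(cell)))
  }
  items <- strsplit(cell, ";", fixed = TRUE)[[1]]
  keys <- character(0)
  values <- character(0)
  for (item in items) {
    if (!nzchar(trimws(item))) next
    eq <- regexpr("=", item, fixed = TRUE)[1]
    if (eq < 0L) {
      key <- "NT"
      value <- trimws(item)
    } else {
      key <- toupper(trimws(substr(item, 1L, eq - 1L)))
      value <- trimws(substr(item, eq + 1L, nchar(item)))
    }
    if (key %in% keys) {
      sdrf_parse_error("duplicate key '%s' in cell '%s'", key, cell)
    }
    keys <- c(keys, key)
    values <- c(values, value)
  }
  names(values) <- keys
  values
}

#' Serialize a key/value map back to cell syntax
#'
#' Inverse of [parse_key_value_cell()] on trimmed input: pairs are joined as
#' `KEY=value` with `;`, in map order.
#'
#' @param kv Named character vector.
#' @return A single cell string.
#' @export
serialize_key_value <- function(kv) {
  stopifnot(is.character(kv), !is.null(names(kv)))
  paste(paste0(names(kv), "=", unname(kv)), collapse = ";")
}

MOD_TYPES <- c("FIXED", "VARIABLE", "ANNOTATED")
MOD_POSITIONS <- c("ANYWHERE", "PROTEIN_N_TERM", "PROTEIN_C_TERM",
                   "ANY_N_TERM", "ANY_C_TERM")
# keys understood by the micro-syntax parsers; others are preserved verbatim
# in the cell and reported by the validator at info level
KNOWN_KV_KEYS <- c("NT", "AC", "MT", "TA", "PP", "MM", "CF", "CS")

#' Construct a protein-modification specification
#'
#' Search-relevant description of one modification: name (`NT`), accession
#' (`AC`, e.g. `UNIMOD:35`), type (`MT`: fixed, variable or annotated),
#' target residues (`TA`), peptide/protein position (`PP`), monoisotopic mass
#' shift in Da (`MM`) and chemical formula (`CF`).
#'
#' @param name Modification name (may be `NULL` if `accession` given).
#' @param accession Optional accession.
#' @param mod_type `"FIXED"`, `"VARIABLE"` (default) or `"ANNOTATED"`.
#' @param target_amino_acids Character vector of single upper-case residue
#'   letters.
#' @param position Optional position enum (`"ANYWHERE"`, `"PROTEIN_N_TERM"`,
#'   `"PROTEIN_C_TERM"`, `"ANY_N_TERM"`, `"ANY_C_TERM"`).
#' @param monoisotopic_mass Optional mass shift in Da.
#' @param chemical_formula Optional formula text.
#' @return An object of class `modification_spec`.
#' @export
modification_spec <- function(name = NULL, accession = NULL,
                              mod_type = "VARIABLE",
                              target_amino_acids = character(0),
                              position = NULL, monoisotopic_mass = NULL,
                              chemical_formula = NULL) {
  if (is.null(name) && is.null(accession)) {
    sdrf_parse_error("modification needs at least a name (NT) or accession (AC)")
  }
  mod_type <- match.arg(toupper(mod_type), MOD_TYPES)
  target_amino_acids <- as.character(target_amino_acids)
  bad <- target_amino_acids[!grepl("^[A-Z]$", target_amino_acids)]
  if (length(bad)) {
    sdrf_parse_error("target amino acids must be single upper-case letters, got: %s",
                     paste(bad, collapse = ", "))
  }
  if (!is.null(position)) {
    position <- match.arg(toupper(position), MOD_POSITIONS)
  }
  if (!is.null(monoisotopic_mass)) {
    monoisotopic_mass <- as.numeric(monoisotopic_mass)
    if (is.na(monoisotopic_mass)) {
      sdrf_parse_error("monoisotopic mass must be numeric")
    }
  }
  structure(
    list(name = name, accession = accession, mod_type = mod_type,
         target_amino_acids = target_amino_acids, position = position,
         monoisotopic_mass = monoisotopic_mass,
         chemical_formula = chemical_formula),
    class = "modification_spec"
  )
}

#' Parse a modification cell
#'
#' Applies [parse_key_value_cell()] and maps the keys onto the
#' [modification_spec()] fields. `MT` matches case-insensitively and defaults
#' to variable when absent (so the bare-name shorthand stays usable); `TA`
#' splits on commas; `MM` is parsed as a decimal number.
#'
#' @param cell Non-empty cell text.
#' @return A [modification_spec()].
#' @export
#' @examples
#' parse_modification("AC=UNIMOD:35;NT=Oxidation;MT=Variable;TA=M")
parse_modification <- function(cell) {
  kv <- parse_key_value_cell(cell)
  if (!any(c("NT", "AC") %in% names(kv))) {
    sdrf_parse_error("modification cell '%s' has neither NT nor AC", cell)
  }
  mt <- if ("MT" %in% names(kv)) toupper(kv[["MT"]]) else "VARIABLE"
  if (!mt %in% MOD_TYPES) {
    sdrf_parse_error("unknown modification type '%s' in cell '%s'",
                     kv[["MT"]], cell)
  }
  ta <- character(0)
  if ("TA" %in% names(kv)) {
    ta <- trimws(strsplit(kv[["TA"]], ",", fixed = TRUE)[[1]])
    ta <- ta[nzchar(ta)]
  }
  pp <- NULL
  if ("PP" %in% names(kv)) {
    pp <- gsub("[ -]", "_", toupper(trimws(kv[["PP"]])))
    if (!pp %in% MOD_POSITIONS) {
      sdrf_parse_error("unknown modification position '%s' in cell '%s'",
                       kv[["PP"]], cell)
    }
  }
  mm <- NULL
  if ("MM" %in% names(kv)) {
    mm <- suppressWarnings(as.numeric(kv[["MM"]]))
    if (is.na(mm)) {
      sdrf_parse_error("non-numeric monoisotopic mass '%s' in cell '%s'",
                       kv[["MM"]], cell)
    }
  }
  modification_spec(
    name = if ("NT" %in% names(kv)) kv[["NT"]] else NULL,
    accession = if ("AC" %in% names(kv)) kv[["AC"]] else NULL,
    mod_type = mt,
    target_amino_acids = ta,
    position = pp,
    monoisotopic_mass = mm,
    chemical_formula = if ("CF" %in% names(kv)) kv[["CF"]] else NULL
  )
}

# canonical human-readable rendering of a position enum
format_mod_position <- function(position) {
  c(ANYWHERE = "Anywhere", PROTEIN_N_TERM = "Protein N-term",
    PROTEIN_C_TERM = "Protein C-term", ANY_N_TERM = "Any N-term",
    ANY_C_TERM = "Any C-term")[[position]]
}

#' Serialize a modification back to cell syntax
#'
#' Emits keys in the order `AC`, `NT`, `MT`, `TA`, `PP`, `MM`, `CF` (absent
#' fields omitted). [parse_modification()] of the result reproduces the
#' specification.
#'
#' @param mod A [modification_spec()].
#' @return A cell string.
#' @export
serialize_modification <- function(mod) {
  stopifnot(inherits(mod, "modification_spec"))
  kv <- character(0)
  if (!is.null(mod$accession)) kv <- c(kv, AC = mod$accession)
  if (!is.null(mod$name)) kv <- c(kv, NT = mod$name)
  kv <- c(kv, MT = c(FIXED = "Fixed", VARIABLE = "Variable",
                     ANNOTATED = "Annotated")[[mod$mod_type]])
  if (length(mod$target_amino_acids)) {
    kv <- c(kv, TA = paste(mod$target_amino_acids, collapse = ","))
  }
  if (!is.null(mod$position)) kv <- c(kv, PP = format_mod_position(mod$position))
  if (!is.null(mod$monoisotopic_mass)) {
    kv <- c(kv, MM = format(mod$monoisotopic_mass, digits = 15,
                            scientific = FALSE, trim = TRUE))
  }
  if (!is.null(mod$chemical_formula)) kv <- c(kv, CF = mod$chemical_formula)
  serialize_key_value(kv)
}

#' Construct / parse a cleavage-agent specification
#'
#' An enzyme has a name (`NT`), an optional accession (`AC`, typically a
#' PSI-MS term) and an optional cleavage-site regular expression (`CS`).
#'
#' @param name Enzyme name; required.
#' @param accession Optional accession.
#' @param cleavage_site Optional cleavage-site regular expression.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, accession = NULL, cleavage_site = NULL) {
  if (is.null(name) || !nzchar(name)) {
    sdrf_parse_error("enzyme name must be non-empty")
  }
  structure(list(name = name, accession = accession,
                 cleavage_site = cleavage_site),
            class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @param cell Non-empty cell text in key/value syntax (or a bare name).
#' @export
#' @examples
#' parse_enzyme("AC=MS:1001251;NT=Trypsin")
parse_enzyme <- function(cell) {
  kv <- parse_key_value_cell(cell)
  if (!"NT" %in% names(kv)) {
    sdrf_parse_error("cleavage-agent cell '%s' has no name (NT)", cell)
  }
  enzyme_spec(
    name = kv[["NT"]],
    accession = if ("AC" %in% names(kv)) kv[["AC"]] else NULL,
    cleavage_site = if ("CS" %in% names(kv)) kv[["CS"]] else NULL
  )
}

#' Parse a mass tolerance
#'
#' Grammar: a positive number followed by a unit, `ppm` or `Da`
#' (case-insensitive), with optional whitespace in between.
#'
#' @param cell Non-empty cell text, e.g. `"20 ppm"` or `"0.5 Da"`.
#' @return An object of class `tolerance` with fields `value` and `unit`
#'   (`"PPM"` or `"DA"`).
#' @export
#' @examples
#' parse_tolerance("20 ppm")
parse_tolerance <- function(cell) {
  if (!is.character(cell) || length(cell) != 1L || is.na(cell) ||
      !nzchar(trimws(cell))) {
    sdrf_parse_error("tolerance cell must be a non-empty string")
  }
  m <- regexec("^\\s*([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*([A-Za-z]*)\\s*$",
               cell)
  parts <- regmatches(cell, m)[[1]]
  if (length(parts) != 3L) {
    sdrf_parse_error("malformed tolerance '%s' (expected '<number> <ppm|Da>')",
                     cell)
  }
  value <- as.numeric(parts[2])
  unit <- tolower(parts[3])
  if (!nzchar(unit)) {
    sdrf_parse_error("tolerance '%s' is missing its unit (ppm or Da)", cell)
  }
  if (!unit %in% c("ppm", "da")) {
    sdrf_parse_error("unknown tolerance unit '%s' in '%s'", parts[3], cell)
  }
  if (is.na(value) || value <= 0) {
    sdrf_parse_error("tolerance value must be positive in '%s'", cell)
  }
  structure(list(value = value, unit = toupper(unit)), class = "tolerance")
}

#' Render a tolerance in canonical cell syntax
#' @param tol A `tolerance` object.
#' @return A cell string such as `"20 ppm"`.
#' @export
format_tolerance <- function(tol) {
  stopifnot(inherits(tol, "tolerance"))
  unit <- c(PPM = "ppm", DA = "Da")[[tol$unit]]
  paste(format(tol$value, digits = 15, scientific = FALSE, trim = TRUE), unit)
}
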