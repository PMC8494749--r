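# SDRF tables: the sample <-> data-file relationship matrix.
#
# Each row of an SDRF file records one relationship between a sample and a
# data file (a RAW file, or one labeling channel of a RAW file). Cells are
# kept verbatim: the reader never trims, types or deduplicates values.

# missing-value tokens: "not available" is emitted, both are recognized
MISSING_TOKENS <- c("not available", "not applicable")

is_missing_cell <- function(x) {
  !nzchar(x) | tolower(trimws(x)) %in% MISSING_TOKENS
}

#' Construct an SDRF table
#'
#' @param columns List of [column_key()] objects, one per column.
#' @param cells Character matrix with one row per sample/file relationship
#'   and `length(columns)` columns.
#' @param provenance Optional source name or path, carried for messages.
#' @return An object of class `sdrf_table`.
#' @export
sdrf_table <- function(columns = list(), cells = NULL, provenance = NULL) {
  stopifnot(is.list(columns),
            all(vapply(columns, inherits, logical(1), "column_key")))
  if (is.null(cells)) {
    cells <- matrix(character(0), nrow = 0L, ncol = length(columns))
  }
  stopifnot(is.matrix(cells), is.character(cells) || length(cells) == 0L)
  if (ncol(cells) != length(columns)) {
    stop("`cells` must have one column per column key", call. = FALSE)
  }
  structure(list(columns = columns, cells = cells, provenance = provenance),
            class = "sdrf_table")
}

#' @export
print.sdrf_table <- function(x, ...) {
  cat(sprintf("<sdrf_table> %d row%s x %d column%s\n",
              nrow(x$cells), if (nrow(x$cells) == 1) "" else "s",
              length(x$columns), if (length(x$columns) == 1) "" else "s"))
  if (length(x$columns)) {
    cat("  ", paste(sdrf_headers(x), collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.sdrf_table <- function(x) c(nrow(x$cells), length(x$columns))

#' Canonical header strings of a table
#' @param table An [sdrf_table()].
#' @return Character vector of canonical headers in column order.
#' @export
sdrf_headers <- function(table) {
  vapply(table$columns, format_column_header, character(1))
}

# indices of columns matching a category (and optionally an attribute)
col_which <- function(table, category, attribute = NULL) {
  hit <- vapply(table$columns, function(k) {
    k$category == category &&
      (is.null(attribute) || k$attribute == attribute)
  }, logical(1))
  which(hit)
}

# single-column accessor; returns NA_integer_ when absent, errors when many
col_one <- function(table, category, attribute = NULL) {
  idx <- col_which(table, category, attribute)
  if (length(idx) == 0L) return(NA_integer_)
  idx[1]
}

# split one physical line into cells, preserving trailing empty cells
split_tsv_line <- function(line) {
  guarded <- paste0(line, "\x1e")
  out <- strsplit(guarded, "\t", fixed = TRUE)[[1]]
  out[length(out)] <- substr(out[length(out)], 1L,
                             nchar(out[length(out)]) - 1L)
  out
}

read_utf8_lines <- function(file) {
  if (is.character(file)) {
    con <- file(file, open = "r", encoding = "UTF-8")
    on.exit(close(con))
  } else {
    con <- file
  }
  sub("\r$", "", readLines(con, warn = FALSE))
}

write_utf8_lines <- function(lines, file) {
  if (is.character(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
  } else {
    con <- file
  }
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
}

# renumber occurrence indices left to right among identical canonical headers
number_occurrences <- function(columns) {
  seen <- integer(0)
  for (i in seq_along(columns)) {
    base <- format_column_header(columns[[i]])
    n <- if (base %in% names(seen)) seen[[base]] + 1L else 1L
    seen[base] <- n
    columns[[i]]$occurrence <- n
  }
  columns
}

#' Read an SDRF file
#'
#' Reads a UTF-8 tab-delimited SDRF file. The first line is the header; each
#' header is parsed with [parse_column_header()] left to right, with
#' occurrence counters incremented for repeated headers. Cell values are kept
#' verbatim. Blank lines at the end of the file are ignored. All malformed
#' headers are aggregated into one error; a data row whose cell count differs
#' from the header is reported with its 1-based line number.
#'
#' @param file Path or connection.
#' @return An [sdrf_table()].
#' @export
read_sdrf <- function(file) {
  lines <- read_utf8_lines(file)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) {
    sdrf_parse_error("empty SDRF input: missing header line")
  }
  header_cells <- split_tsv_line(lines[1])
  columns <- vector("list", length(header_cells))
  header_errors <- character(0)
  for (i in seq_along(header_cells)) {
    parsed <- tryCatch(parse_column_header(header_cells[i]),
                       sdrf_parse_error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      header_errors <- c(header_errors, sprintf("column %d: %s", i, parsed))
    } else {
      columns[[i]] <- parsed
    }
  }
  if (length(header_errors)) {
    sdrf_parse_error("invalid SDRF header:\n  %s",
                     paste(header_errors, collapse = "\n  "))
  }
  columns <- number_occurrences(columns)
  n_col <- length(columns)
  body <- lines[-1]
  cells <- matrix(character(0), nrow = 0L, ncol = n_col)
  if (length(body)) {
    rows <- lapply(body, split_tsv_line)
    lens <- lengths(rows)
    bad <- which(lens != n_col)
    if (length(bad)) {
      sdrf_parse_error("line %d: expected %d cells but found %d",
                       bad[1] + 1L, n_col, lens[bad[1]])
    }
    cells <- matrix(unlist(rows), nrow = length(rows), ncol = n_col,
                    byrow = TRUE)
  }
  sdrf_table(columns, cells,
             provenance = if (is.character(file)) file else NULL)
}

#' Reorder columns into the canonical section layout
#'
#' Canonical SDRF files read in three sections: the sample metadata
#' (`source name`, then all characteristics), the data-file properties
#' (`assay name`, then all comments) and the variables under study (factor
#' values) last. Ordering is stable within each section. [write_sdrf()]
#' applies this layout; the reader accepts any column order.
#'
#' @param table An [sdrf_table()].
#' @return The table with reordered columns.
#' @export
sdrf_canonicalize <- function(table) {
  stopifnot(inherits(table, "sdrf_table"))
  section <- match(vapply(table$columns, `[[`, "", "category"),
                   c("SOURCE_NAME", "CHARACTERISTICS", "ASSAY_NAME",
                     "COMMENT", "FACTOR_VALUE"))
  ord <- order(section, seq_along(section))
  sdrf_table(table$columns[ord], table$cells[, ord, drop = FALSE],
             provenance = table$provenance)
}

#' Write an SDRF file
#'
#' Emits canonical headers ([format_column_header()]) in the canonical
#' section order ([sdrf_canonicalize()]), tab-separated cells, `\n` line
#' endings and UTF-8 encoding, with no trailing blank line. Reading the
#' output back yields the canonicalized table.
#'
#' @param table An [sdrf_table()].
#' @param file Path or connection.
#' @return The canonicalized table, invisibly.
#' @export
write_sdrf <- function(table, file) {
  stopifnot(inherits(table, "sdrf_table"))
  table <- sdrf_canonicalize(table)
  bad <- grepl("[\t\n\r]", table$cells)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(table$cells))
    sdrf_parse_error("cell at row %d, column '%s' embeds a tab or newline",
                     idx[1, 1],
                     format_column_header(table$columns[[idx[1, 2]]]))
  }
  header <- paste(sdrf_headers(table), collapse = "\t")
  body <- if (nrow(table$cells)) {
    apply(table$cells, 1L, paste, collapse = "\t")
  } else {
    character(0)
  }
  write_utf8_lines(c(header, body), file)
  invisible(table)
}

#' Per-sample view of an SDRF table
#'
#' One row per distinct source name, in first-appearance order. With
#' fractionation or technical replication the same sample spans several SDRF
#' rows; `row_indices` lists them all, and the characteristics map is taken
#' from the first row of the group.
#'
#' @param table An [sdrf_table()] with a `source name` column.
#' @return A tibble with columns `source_name`, `characteristics` (list of
#'   named character vectors, attribute to cell text) and `row_indices`
#'   (list of integer vectors).
#' @export
samples_of <- function(table) {
  stopifnot(inherits(table, "sdrf_table"))
  src <- col_one(table, "SOURCE_NAME")
  if (is.na(src)) {
    sdrf_parse_error("table has no 'source name' column")
  }
  char_idx <- col_which(table, "CHARACTERISTICS")
  char_names <- vapply(char_idx, function(i) table$columns[[i]]$attribute,
                       character(1))
  names_seen <- unique(table$cells[, src])
  rows_by_name <- split(seq_len(nrow(table$cells)),
                        factor(table$cells[, src], levels = names_seen))
  characteristics <- lapply(names_seen, function(nm) {
    first <- rows_by_name[[nm]][1]
    stats::setNames(table$cells[first, char_idx], char_names)
  })
  tibble::tibble(
    source_name = names_seen,
    characteristics = characteristics,
    row_indices = unname(rows_by_name)
  )
}

#' Per-assay view of an SDRF table
#'
#' One row per distinct (data file, label) pair in first-appearance order. In
#' multiplexed designs several labeled samples share one data file, so the
#' pair — not the file alone — identifies an assay. When the table has no
#' `comment[label]` column every row is an unlabeled run and the label
#' defaults to `"label free sample"`.
#'
#' @param table An [sdrf_table()] with a `comment[data file]` column.
#' @return A tibble with columns `data_file`, `label`, `comments` (list of
#'   named character vectors) and `row_indices` (list of integer vectors).
#' @export
assays_of <- function(table) {
  stopifnot(inherits(table, "sdrf_table"))
  file_idx <- col_one(table, "COMMENT", "data file")
  if (is.na(file_idx)) {
    sdrf_parse_error("table has no 'comment[data file]' column")
  }
  label_idx <- col_one(table, "COMMENT", "label")
  n <- nrow(table$cells)
  files <- table$cells[, file_idx]
  labels <- if (is.na(label_idx)) rep("label free sample", n)
            else table$cells[, label_idx]
  key <- paste(files, labels, sep = "\x1f")
  keys_seen <- unique(key)
  rows_by_key <- split(seq_len(n), factor(key, levels = keys_seen))
  com_idx <- col_which(table, "COMMENT")
  com_names <- vapply(com_idx, function(i) table$columns[[i]]$attribute,
                      character(1))
  first_rows <- vapply(rows_by_key, `[`, integer(1), 1L)
  comments <- lapply(first_rows, function(r) {
    stats::setNames(table$cells[r, com_idx], com_names)
  })
  tibble::tibble(
    data_file = files[first_rows],
    label = labels[first_rows],
    comments = unname(comments),
    row_indices = unname(rows_by_key)
  )
}

# characteristics map (attribute#occurrence -> value) of each source name,
# from its first row; used for cross-table collision checks
source_characteristics <- function(table) {
  src <- col_one(table, "SOURCE_NAME")
  if (is.na(src) || !nrow(table$cells)) return(list())
  char_idx <- col_which(table, "CHARACTERISTICS")
  ids <- vapply(char_idx, function(i) column_id(table$columns[[i]]),
                character(1))
  out <- list()
  for (r in seq_len(nrow(table$cells))) {
    nm <- table$cells[r, src]
    if (!nm %in% names(out)) {
      out[[nm]] <- stats::setNames(table$cells[r, char_idx], ids)
    }
  }
  out
}

#' Merge SDRF tables
#'
#' Concatenates tables for meta-analysis. Output columns are the union of the
#' input columns (matched by canonical header and occurrence) in
#' first-appearance order; rows are concatenated in input order; cells for
#' columns absent from a source table are filled with `"not available"`.
#' Samples must stay unambiguous: a source name used in more than one table
#' with conflicting characteristic values is an error.
#'
#' @param ... [sdrf_table()] objects, or lists of them.
#' @return The merged [sdrf_table()].
#' @export
merge_sdrf <- function(...) {
  args <- list(...)
  tables <- list()
  for (a in args) {
    if (inherits(a, "sdrf_table")) tables <- c(tables, list(a))
    else if (is.list(a)) tables <- c(tables, a)
    else stop("merge_sdrf() takes sdrf_table objects", call. = FALSE)
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "sdrf_table")))
  if (!length(tables)) return(sdrf_table())

  # collision check on sample identity
  seen_chars <- list()
  conflicts <- character(0)
  for (tb in tables) {
    for (nm in names(chars <- source_characteristics(tb))) {
      if (nm %in% names(seen_chars)) {
        prev <- seen_chars[[nm]]
        shared <- intersect(names(prev), names(chars[[nm]]))
        if (any(prev[shared] != chars[[nm]][shared])) {
          conflicts <- c(conflicts, nm)
        }
      } else {
        seen_chars[[nm]] <- chars[[nm]]
      }
    }
  }
  if (length(conflicts)) {
    sdrf_parse_error(
      "conflicting characteristics for source name(s): %s",
      paste(unique(conflicts), collapse = ", "))
  }

  out_cols <- list()
  out_ids <- character(0)
  for (tb in tables) {
    for (k in tb$columns) {
      id <- column_id(k)
      if (!id %in% out_ids) {
        out_ids <- c(out_ids, id)
        out_cols <- c(out_cols, list(k))
      }
    }
  }
  total_rows <- sum(vapply(tables, function(tb) nrow(tb$cells), integer(1)))
  cells <- matrix("not available", nrow = total_rows, ncol = length(out_cols))
  at <- 0L
  for (tb in tables) {
    nr <- nrow(tb$cells)
    if (nr == 0L) next
    ids <- vapply(tb$columns, column_id, character(1))
    cells[at + seq_len(nr), match(ids, out_ids)] <- tb$cells
    at <- at + nr
  }
  sdrf_table(out_cols, cells)
}

#' Split an SDRF table by a column's values
#'
#' Partitions the rows by the distinct values of one column (e.g. split a
#' dataset by `comment[fraction identifier]` or by a sample property). Each
#' sub-table keeps all columns and the original relative row order;
#' concatenating the sub-tables in first-appearance order of the values
#' reconstructs the input rows.
#'
#' @param table An [sdrf_table()].
#' @param by A canonical header string or [column_key()] naming the split
#'   column.
#' @return A named list of [sdrf_table()] objects, one per distinct value,
#'   in first-appearance order.
#' @export
split_sdrf <- function(table, by) {
  stopifnot(inherits(table, "sdrf_table"))
  key <- if (inherits(by, "column_key")) by else parse_column_header(by)
  idx <- which(vapply(table$columns, keys_equal, logical(1), key))
  if (!length(idx)) {
    sdrf_parse_error("split column '%s' not present in table",
                     format_column_header(key))
  }
  idx <- idx[1]
  values <- table$cells[, idx]
  levels_seen <- unique(values)
  out <- lapply(levels_seen, function(v) {
    sdrf_table(table$columns,
               table$cells[values == v, , drop = FALSE],
               provenance = table$provenance)
  })
  stats::setNames(out, levels_seen)
}

#' Drop a column from an SDRF table
#'
#' Convenience editor used when thinning a table (for instance to probe how
#' validation reacts to a missing required column).
#'
#' @param table An [sdrf_table()].
#' @param header Canonical header string or [column_key()].
#' @return The table without that column.
#' @export
sdrf_drop_column <- function(table, header) {
  key <- if (inherits(header, "column_key")) header
         else parse_column_header(header)
  idx <- which(vapply(table$columns, keys_equal, logical(1), key))
  if (!length(idx)) {
    sdrf_parse_error("column '%s' not present in table",
                     format_column_header(key))
  }
  sdrf_table(number_occurrences(table$columns[-idx[1]]),
             table$cells[, -idx[1], drop = FALSE],
             provenance = table$provenance)
}

#' Add or overwrite a column in an SDRF table
#'
#' @param table An [sdrf_table()].
#' @param header Canonical header string or [column_key()].
#' @param values Character vector recycled to the row count.
#' @return The extended table.
#' @export
sdrf_set_column <- function(table, header, values) {
  key <- if (inherits(header, "column_key")) header
         else parse_column_header(header)
  values <- rep_len(as.character(values), nrow(table$cells))
  idx <- which(vapply(table$columns, keys_equal, logical(1), key))
  if (length(idx)) {
    table$cells[, idx[1]] <- values
    return(table)
  }
  sdrf_table(number_occurrences(c(table$columns, list(key))),
             cbind(table$cells, values, deparse.level = 0),
             provenance = table$provenance)
}
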