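# Experimental-design generation.
#
# A compact design specification (quantification method x biological
# replicates x technical replicates x fractions) expands deterministically
# into a complete, valid SDRF table. One SDRF row is one sample <-> file
# relationship, so samples repeat across the fractions of a run and file
# properties repeat across the labeling channels of a multiplexed run.

QUANT_METHODS <- c("LABEL_FREE", "TMT6", "TMT10", "TMT11", "SILAC2", "SILAC3")

plex_size <- function(quant_method) {
  c(LABEL_FREE = 1L, TMT6 = 6L, TMT10 = 10L, TMT11 = 11L,
    SILAC2 = 2L, SILAC3 = 3L)[[quant_method]]
}

channel_names <- function(quant_method) {
  switch(quant_method,
    LABEL_FREE = "label free sample",
    TMT6 = tmt_channels(6),
    TMT10 = tmt_channels(10),
    TMT11 = tmt_channels(11),
    SILAC2 = c("SILAC light", "SILAC heavy"),
    SILAC3 = c("SILAC light", "SILAC medium", "SILAC heavy")
  )
}

#' Construct an experimental-design specification
#'
#' Parameters of a synthetic proteomics design: the quantification method
#' (label-free, TMT 6/10/11-plex, SILAC 2/3-plex), the numbers of biological
#' replicates, technical replicates per sample and fractions per run, sample
#' metadata (organism, organism part), and the study variable with its
#' levels (assigned to biological replicates round-robin).
#'
#' @param quant_method One of `"LABEL_FREE"`, `"TMT6"`, `"TMT10"`,
#'   `"TMT11"`, `"SILAC2"`, `"SILAC3"`.
#' @param n_biological Biological replicates (samples), >= 1.
#' @param n_technical Technical replicates (re-injections) per run, >= 1.
#' @param n_fractions Fractions per run, >= 1.
#' @param organism Sample organism.
#' @param organism_part Sampled organ/tissue.
#' @param factor_name Name of the variable under study.
#' @param factor_levels Non-empty character vector of factor levels.
#' @param file_prefix Stem used for generated RAW file names.
#' @param seed Reserved for future randomized layouts; generation is
#'   deterministic.
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' design_spec("TMT6", n_biological = 3, n_fractions = 3)
design_spec <- function(quant_method = "LABEL_FREE", n_biological = 2L,
                        n_technical = 1L, n_fractions = 1L,
                        organism = "Homo sapiens", organism_part = "liver",
                        factor_name = "phenotype",
                        factor_levels = c("normal", "disease"),
                        file_prefix = "file", seed = NULL) {
  quant_method <- match.arg(toupper(quant_method), QUANT_METHODS)
  n_biological <- as.integer(n_biological)
  n_technical <- as.integer(n_technical)
  n_fractions <- as.integer(n_fractions)
  if (any(is.na(c(n_biological, n_technical, n_fractions))) ||
      n_biological < 1L || n_technical < 1L || n_fractions < 1L) {
    stop("replicate and fraction counts must be positive integers",
         call. = FALSE)
  }
  factor_levels <- as.character(factor_levels)
  if (!length(factor_levels)) {
    stop("`factor_levels` must be non-empty", call. = FALSE)
  }
  structure(
    list(quant_method = quant_method, n_biological = n_biological,
         n_technical = n_technical, n_fractions = n_fractions,
         organism = organism, organism_part = organism_part,
         factor_name = tolower(squish(factor_name)),
         factor_levels = factor_levels, file_prefix = file_prefix,
         seed = seed),
    class = "design_spec"
  )
}

#' Expected number of SDRF rows for a design
#'
#' One row per sample-file relationship: biological replicates x technical
#' replicates x fractions, for every supported quantification method. (In a
#' multiplexed design there are fewer files, but each file carries one row
#' per channel, so the product is unchanged.)
#'
#' @param spec A [design_spec()].
#' @return Integer row count.
#' @export
expected_row_count <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  spec$n_biological * spec$n_technical * spec$n_fractions
}

#' Generate a complete SDRF table from a design specification
#'
#' Expansion semantics: samples are packed into mixtures of at most the plex
#' size (label-free runs hold one sample); one data file is produced per
#' (mixture, technical replicate, fraction), named
#' `{file_prefix}_{mixture}_{t}_{f}.raw`; each file contributes one row per
#' sample in its mixture, with the sample's channel in `comment[label]` and
#' fraction identifiers running 1..F within each (mixture, technical
#' replicate) group. Channels are assigned in fixed channel-list order, and
#' technical re-injections of a mixture reuse the same sample-to-channel
#' map. Factor levels go to biological replicates round-robin. The output
#' has [expected_row_count()] rows and validates with zero errors under the
#' default template.
#'
#' @param spec A [design_spec()].
#' @return An [sdrf_table()].
#' @export
#' @examples
#' tab <- generate_design(design_spec("TMT6", n_biological = 3, n_fractions = 3))
#' dim(tab)
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  S <- spec$n_biological
  Tn <- spec$n_technical
  Fn <- spec$n_fractions
  plex <- plex_size(spec$quant_method)
  channels <- channel_names(spec$quant_method)
  if (spec$quant_method %in% c("SILAC2", "SILAC3") && S %% plex != 0L) {
    stop(sprintf(
      "SILAC designs need n_biological divisible by the channel count (%d); got %d",
      plex, S), call. = FALSE)
  }
  n_mix <- ceiling(S / plex)

  columns <- number_occurrences(list(
    column_key("SOURCE_NAME"),
    column_key("CHARACTERISTICS", "organism"),
    column_key("CHARACTERISTICS", "organism part"),
    column_key("CHARACTERISTICS", "biological replicate"),
    column_key("CHARACTERISTICS", spec$factor_name),
    column_key("ASSAY_NAME"),
    column_key("COMMENT", "label"),
    column_key("COMMENT", "fraction identifier"),
    column_key("COMMENT", "technical replicate"),
    column_key("COMMENT", "data file"),
    column_key("COMMENT", "instrument"),
    column_key("FACTOR_VALUE", spec$factor_name)
  ))

  level_of <- function(i) {
    spec$factor_levels[(i - 1L) %% length(spec$factor_levels) + 1L]
  }
  channel_of <- function(i) channels[(i - 1L) %% plex + 1L]
  instrument <- "NT=Q Exactive;AC=MS:1001911"

  rows <- vector("list", expected_row_count(spec))
  at <- 0L
  file_no <- 0L
  for (m in seq_len(n_mix)) {
    samples <- seq.int((m - 1L) * plex + 1L, min(m * plex, S))
    for (t in seq_len(Tn)) {
      for (f in seq_len(Fn)) {
        file_no <- file_no + 1L
        data_file <- sprintf("%s_%d_%d_%d.raw", spec$file_prefix, m, t, f)
        assay <- sprintf("run %d", file_no)
        for (i in samples) {
          at <- at + 1L
          rows[[at]] <- c(
            sprintf("sample %d", i),
            spec$organism,
            spec$organism_part,
            as.character(i),
            level_of(i),
            assay,
            channel_of(i),
            as.character(f),
            as.character(t),
            data_file,
            instrument,
            level_of(i)
          )
        }
      }
    }
  }
  cells <- matrix(unlist(rows), nrow = at, ncol = length(columns),
                  byrow = TRUE)
  sdrf_table(columns, cells, provenance = sprintf("generated:%s S=%d T=%d F=%d",
                                                  spec$quant_method, S, Tn, Fn))
}

#' Read a design specification from a flat key:value file
#'
#' One `key: value` pair per line; keys match the [design_spec()] arguments
#' (`quant_method`, `n_biological`, `n_technical`, `n_fractions`,
#' `organism`, `organism_part`, `factor_name`, `factor_levels`,
#' `file_prefix`). `factor_levels` is comma-separated. Empty lines and `#`
#' comments are ignored.
#'
#' @param file Path or connection.
#' @return A [design_spec()].
#' @export
read_design_spec <- function(file) {
  lines <- read_utf8_lines(file)
  args <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    sep <- regexpr(":", line, fixed = TRUE)[1]
    if (sep < 0L) {
      sdrf_parse_error("line %d: expected 'key: value'", i)
    }
    key <- trimws(substr(line, 1L, sep - 1L))
    value <- trimws(substr(line, sep + 1L, nchar(line)))
    args[[key]] <- value
  }
  known <- c("quant_method", "n_biological", "n_technical", "n_fractions",
             "organism", "organism_part", "factor_name", "factor_levels",
             "file_prefix", "seed")
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    sdrf_parse_error("unknown design key(s): %s", paste(bad, collapse = ", "))
  }
  for (k in c("n_biological", "n_technical", "n_fractions", "seed")) {
    if (!is.null(args[[k]])) args[[k]] <- as.integer(args[[k]])
  }
  if (!is.null(args$factor_levels)) {
    args$factor_levels <- trimws(strsplit(args$factor_levels, ",",
                                          fixed = TRUE)[[1]])
  }
  do.call(design_spec, args)
}
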