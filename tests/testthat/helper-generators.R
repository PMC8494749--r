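# Randomized-case generators shared by the property-style tests.
# All draw from the current RNG stream; tests set a fixed seed.

rand_from <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# a syntactically valid header in a random real-world dialect
# (random case, optional space before '[' and padding inside brackets)
random_header <- function() {
  category <- rand_from(c("SOURCE_NAME", "CHARACTERISTICS", "COMMENT",
                          "FACTOR_VALUE", "ASSAY_NAME"))
  attrs <- c("organism", "organism part", "disease", "cell line",
             "instrument", "fraction identifier", "technical replicate",
             "data file", "label", "modification parameters", "phenotype",
             "ancestry", "cleavage agent", "spiked compound")
  randomize_case <- function(x) {
    chars <- strsplit(x, "")[[1]]
    flip <- runif(length(chars)) < 0.5
    chars[flip] <- toupper(chars[flip])
    paste(chars, collapse = "")
  }
  if (category %in% c("SOURCE_NAME", "ASSAY_NAME")) {
    base <- if (category == "SOURCE_NAME") "source name" else "assay name"
    return(list(text = randomize_case(base),
                key = column_key(category)))
  }
  attribute <- rand_from(attrs)
  prefix <- switch(category, CHARACTERISTICS = "characteristics",
                   COMMENT = "comment", FACTOR_VALUE = "factor value")
  pad1 <- rand_from(c("", " ", "  "))
  pad2 <- rand_from(c("", " "))
  pad3 <- rand_from(c("", " "))
  list(
    text = paste0(randomize_case(prefix), pad1, "[", pad2,
                  randomize_case(attribute), pad3, "]"),
    key = column_key(category, attribute)
  )
}

# a random ordered key/value map with unique keys and delimiter-free values
random_kv_map <- function() {
  n <- sample.int(5L, 1L)
  keys <- sample(c("AC", "NT", "MT", "TA", "PP", "MM", "CF", "CS", "TS",
                   "XX"), n)
  values <- vapply(seq_len(n), function(i) {
    paste(sample(c(letters, LETTERS, 0:9, ":", ".", " "),
                 sample.int(12L, 1L), replace = TRUE), collapse = "")
  }, character(1))
  values <- trimws(values)
  values[!nzchar(values)] <- "x"
  stats::setNames(values, keys)
}

# a random well-formed modification specification
random_modification <- function() {
  has_name <- runif(1) < 0.9
  has_acc <- !has_name || runif(1) < 0.6
  n_ta <- sample.int(4L, 1L) - 1L
  modification_spec(
    name = if (has_name) rand_from(c("Oxidation", "Phospho", "Acetyl",
                                     "Carbamidomethyl", "Deamidated")),
    accession = if (has_acc) sprintf("UNIMOD:%d", sample.int(2000L, 1L)),
    mod_type = rand_from(c("FIXED", "VARIABLE", "ANNOTATED")),
    target_amino_acids = if (n_ta) sample(LETTERS, n_ta) else character(0),
    position = if (runif(1) < 0.5) {
      rand_from(c("ANYWHERE", "PROTEIN_N_TERM", "PROTEIN_C_TERM",
                  "ANY_N_TERM", "ANY_C_TERM"))
    },
    monoisotopic_mass = if (runif(1) < 0.5) {
      round(stats::runif(1, 0.5, 500), 4)
    },
    chemical_formula = if (runif(1) < 0.3) rand_from(c("O", "HPO3", "C2H2O"))
  )
}

# a random valid design specification with small dimensions
random_design_spec <- function(max_dim = 5L) {
  method <- rand_from(c("LABEL_FREE", "TMT6", "TMT10", "TMT11",
                        "SILAC2", "SILAC3"))
  plex <- switch(method, LABEL_FREE = 1L, TMT6 = 6L, TMT10 = 10L,
                 TMT11 = 11L, SILAC2 = 2L, SILAC3 = 3L)
  s <- sample.int(max_dim, 1L)
  if (startsWith(method, "SILAC")) s <- s * plex  # full channel complements
  design_spec(
    quant_method = method,
    n_biological = s,
    n_technical = sample.int(max_dim, 1L),
    n_fractions = sample.int(max_dim, 1L),
    organism = rand_from(c("Homo sapiens", "Mus musculus")),
    organism_part = rand_from(c("liver", "brain", "blood")),
    factor_name = rand_from(c("phenotype", "compound", "disease")),
    factor_levels = sample(c("normal", "disease", "treated", "vehicle"),
                           sample.int(3L, 1L) + 1L),
    file_prefix = rand_from(c("file", "run", "batch1"))
  )
}

# strip class/provenance differences for table-content comparisons
table_fingerprint <- function(table) {
  list(headers = sdrf_headers(table), cells = unname(table$cells))
}

# rows of a table as a sorted multiset of row-strings
row_multiset <- function(table) {
  if (!nrow(table$cells)) return(character(0))
  sort(unname(apply(table$cells, 1L, paste, collapse = "\x1f")))
}
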