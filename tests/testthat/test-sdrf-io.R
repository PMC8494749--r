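# SDRF reading, writing, views, merge and split.

minimal_sdrf_text <- "source name\tcharacteristics[organism]\nsample 1\tHomo sapiens\n"

write_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".sdrf.tsv",
                                .local_envir = parent.frame())
  writeLines(sub("\n$", "", text), path)
  path
}

test_that("a minimal SDRF file reads into a 1x2 table with verbatim cells", {
  tab <- read_sdrf(write_text(minimal_sdrf_text))
  expect_equal(dim(tab), c(1L, 2L))
  expect_equal(sdrf_headers(tab),
               c("source name", "characteristics[organism]"))
  expect_equal(tab$cells[1, ], c("sample 1", "Homo sapiens"))
})

test_that("ragged rows are reported with their 1-based line number", {
  path <- write_text("source name\tcharacteristics[organism]\na\tb\tc\n")
  expect_error(read_sdrf(path), "line 2", class = "sdrf_parse_error")
})

test_that("header failures are aggregated into one report", {
  path <- write_text("source name\tbad[one\tworse[two\nx\ty\tz\n")
  err <- tryCatch(read_sdrf(path), sdrf_parse_error = identity)
  expect_s3_class(err, "sdrf_parse_error")
  expect_match(conditionMessage(err), "column 2")
  expect_match(conditionMessage(err), "column 3")
})

test_that("repeated headers get increasing occurrence indices", {
  path <- write_text(paste0(
    "source name\tcomment[modification parameters]\t",
    "comment[modification parameters]\ns\tOxidation\tPhospho\n"))
  tab <- read_sdrf(path)
  occ <- vapply(tab$columns, function(k) k$occurrence, integer(1))
  expect_equal(occ, c(1L, 1L, 2L))
})

test_that("write then read is the identity on generated designs", {
  set.seed(99)
  for (i in seq_len(100L)) {
    tab <- generate_design(random_design_spec())
    path <- withr::local_tempfile(fileext = ".sdrf.tsv")
    write_sdrf(tab, path)
    expect_equal(table_fingerprint(read_sdrf(path)), table_fingerprint(tab))
  }
})

test_that("cells embedding delimiters are refused on write", {
  tab <- sdrf_table(list(column_key("SOURCE_NAME")),
                    matrix("a\tb", 1, 1))
  expect_error(write_sdrf(tab, tempfile()), "tab",
               class = "sdrf_parse_error")
  empty_rows <- sdrf_table(list(column_key("SOURCE_NAME")))
  path <- withr::local_tempfile()
  write_sdrf(empty_rows, path)
  expect_equal(readLines(path), "source name")
})

test_that("the per-sample view groups rows by source name", {
  tab <- generate_design(design_spec("TMT6", n_biological = 3,
                                     n_fractions = 3))
  sv <- samples_of(tab)
  expect_equal(nrow(sv), 3L)
  expect_equal(lengths(sv$row_indices), rep(3L, 3))
  expect_equal(sv$characteristics[[1]][["organism"]], "Homo sapiens")

  # permuting rows preserves the source-name -> row-count mapping
  perm <- sample(nrow(tab$cells))
  shuffled <- sdrf_table(tab$columns, tab$cells[perm, , drop = FALSE])
  sv2 <- samples_of(shuffled)
  counts <- function(v) sort(stats::setNames(lengths(v$row_indices),
                                             v$source_name))
  expect_equal(counts(sv2), counts(sv))
})

test_that("the per-assay view keys on the (data file, label) pair", {
  tmt <- generate_design(design_spec("TMT6", n_biological = 3,
                                     n_fractions = 3))
  av <- assays_of(tmt)
  expect_equal(nrow(av), 9L)  # 3 files x 3 channels
  expect_equal(length(unique(av$data_file)), 3L)
  expect_false(any(duplicated(paste(av$data_file, av$label))))

  lf <- generate_design(design_spec("LABEL_FREE", n_biological = 2,
                                    n_technical = 2))
  av_lf <- assays_of(lf)
  expect_equal(nrow(av_lf), 4L)
  expect_true(all(av_lf$label == "label free sample"))

  empty <- sdrf_table(list(column_key("COMMENT", "data file")))
  expect_equal(nrow(assays_of(empty)), 0L)
})

test_that("merge concatenates rows, unions columns and fills gaps", {
  a <- generate_design(design_spec("LABEL_FREE", n_biological = 2,
                                   n_technical = 2, file_prefix = "a"))
  b <- generate_design(design_spec("LABEL_FREE", n_biological = 2,
                                   n_technical = 2, file_prefix = "b",
                                   organism = "Mus musculus"))
  # disjoint sample names are required for an unambiguous merge
  b <- sdrf_set_column(b, "source name",
                       paste0("mouse ", b$cells[, 1]))
  merged <- merge_sdrf(a, b)
  expect_equal(nrow(merged$cells), 8L)
  expect_equal(table_fingerprint(merge_sdrf(a, sdrf_table())),
               table_fingerprint(a))

  # a column unique to one input is padded with the missing token
  extra <- sdrf_set_column(a, "characteristics[disease]", "normal")
  merged2 <- merge_sdrf(extra, b)
  di <- which(sdrf_headers(merged2) == "characteristics[disease]")
  expect_equal(merged2$cells[5:8, di], rep("not available", 4))
})

test_that("merge refuses colliding source names with conflicting metadata", {
  a <- generate_design(design_spec("LABEL_FREE"))
  b <- generate_design(design_spec("LABEL_FREE", organism = "Mus musculus"))
  expect_error(merge_sdrf(a, b), "sample 1", class = "sdrf_parse_error")
  # identical characteristics are not a conflict
  expect_silent(merged <- merge_sdrf(a, a))
  expect_equal(nrow(merged$cells), 2L * nrow(a$cells))
})

test_that("split partitions rows by value and split-merge preserves the row multiset", {
  tab <- generate_design(design_spec("TMT6", n_biological = 3,
                                     n_fractions = 3))
  parts <- split_sdrf(tab, "comment[fraction identifier]")
  expect_equal(length(parts), 3L)
  expect_equal(unname(vapply(parts, function(p) nrow(p$cells), integer(1))),
               rep(3L, 3))
  # disjoint and jointly exhaustive
  all_rows <- unname(unlist(lapply(parts, row_multiset)))
  expect_equal(sort(all_rows), row_multiset(tab))
  # each sub-table keeps the original relative row order
  whole <- apply(tab$cells, 1L, paste, collapse = "\x1f")
  for (p in parts) {
    part_rows <- apply(p$cells, 1L, paste, collapse = "\x1f")
    expect_equal(part_rows, whole[whole %in% part_rows])
  }

  # split by a constant column yields the table back
  const <- split_sdrf(tab, "characteristics[organism]")
  expect_equal(length(const), 1L)
  expect_equal(table_fingerprint(const[[1]]), table_fingerprint(tab))

  expect_error(split_sdrf(tab, "comment[absent]"), "absent",
               class = "sdrf_parse_error")
})

test_that("split then merge reproduces the multiset of rows over random designs", {
  set.seed(2024)
  for (i in seq_len(25L)) {
    tab <- generate_design(random_design_spec())
    by <- rand_from(c("comment[fraction identifier]", "source name",
                      "comment[data file]", "comment[label]"))
    parts <- split_sdrf(tab, by)
    back <- merge_sdrf(parts)
    expect_equal(sdrf_headers(back), sdrf_headers(tab))
    expect_equal(row_multiset(back), row_multiset(tab))
  }
})
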