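# Structural, template and vocabulary validation.

valid_lf <- function() {
  generate_design(design_spec("LABEL_FREE", n_biological = 2,
                              n_technical = 2))
}
valid_tmt <- function() {
  generate_design(design_spec("TMT6", n_biological = 3, n_fractions = 3))
}
errors_of <- function(findings) findings[findings$severity == "ERROR", ]

test_that("generated designs carry zero structural errors", {
  for (tab in list(valid_lf(), valid_tmt())) {
    expect_equal(nrow(errors_of(validate_structure(tab))), 0L)
  }
})

test_that("each missing mandatory column fires its rule", {
  tab <- valid_lf()
  cases <- list(
    list("characteristics[organism]", "S3"),
    list("characteristics[organism part]", "S3"),
    list("characteristics[biological replicate]", "S3"),
    list("comment[fraction identifier]", "S4"),
    list("comment[technical replicate]", "S4"),
    list("comment[label]", "S14")
  )
  for (case in cases) {
    f <- validate_structure(sdrf_drop_column(tab, case[[1]]))
    hits <- errors_of(f)
    expect_true(case[[2]] %in% hits$rule_id, info = case[[1]])
    expect_true(case[[1]] %in% hits$column, info = case[[1]])
  }
  # the data-file column is mandated by both its presence rules
  f <- errors_of(validate_structure(sdrf_drop_column(tab,
                                                     "comment[data file]")))
  expect_setequal(intersect(f$rule_id, c("S2", "S4")), c("S2", "S4"))
})

test_that("identifier-column multiplicity is enforced", {
  tab <- valid_lf()
  f <- errors_of(validate_structure(sdrf_drop_column(tab, "source name")))
  expect_true("S1" %in% f$rule_id)
})

test_that("fraction identifiers must be positive integers", {
  tab <- valid_tmt()
  fi <- which(sdrf_headers(tab) == "comment[fraction identifier]")
  tab$cells[4, fi] <- "a"
  f <- errors_of(validate_structure(tab))
  expect_true(any(f$rule_id == "S6" & f$row == 4L))
  tab$cells[4, fi] <- "0"
  expect_true("S6" %in% errors_of(validate_structure(tab))$rule_id)
})

test_that("empty cells in required columns are flagged", {
  tab <- valid_lf()
  oi <- which(sdrf_headers(tab) == "characteristics[organism]")
  tab$cells[2, oi] <- "not available"
  f <- errors_of(validate_structure(tab))
  expect_true(any(f$rule_id == "S5" & f$row == 2L))
})

test_that("sample properties must agree across the rows of one source name", {
  tab <- valid_tmt()
  oi <- which(sdrf_headers(tab) == "characteristics[organism part]")
  rows <- samples_of(tab)$row_indices[[1]]
  tab$cells[rows[2], oi] <- "brain"
  f <- errors_of(validate_structure(tab))
  expect_true("S7" %in% f$rule_id)
})

test_that("file properties must agree across the rows of one data file", {
  tab <- sdrf_table(
    number_occurrences(list(
      column_key("SOURCE_NAME"),
      column_key("ASSAY_NAME"),
      column_key("COMMENT", "data file"),
      column_key("COMMENT", "fraction identifier")
    )),
    matrix(c("s1", "run 1", "f.raw", "1",
             "s2", "run 1", "f.raw", "2"), 2, 4, byrow = TRUE))
  f <- validate_structure(tab)
  # brute-force grouping: the one shared file has two fraction values
  expect_true(any(f$rule_id == "S8" & f$severity == "ERROR"))
})

test_that("one (data file, label) pair maps to one source name", {
  tab <- valid_tmt()
  li <- which(sdrf_headers(tab) == "comment[label]")
  tab$cells[2, li] <- tab$cells[1, li]  # two samples on one channel of a file
  f <- errors_of(validate_structure(tab))
  expect_true("S9" %in% f$rule_id)
})

test_that("advisory rules report at their severities", {
  tab <- valid_lf()
  f <- validate_structure(tab)
  # recommended search-parameter columns are warnings, never errors
  expect_true(all(f$severity[f$rule_id == "S10"] == "WARNING"))
  expect_true("comment[cleavage agent]" %in% f$column[f$rule_id == "S10"])

  li <- which(sdrf_headers(tab) == "comment[label]")
  tab$cells[1, li] <- "TMT999"
  f2 <- validate_structure(tab)
  expect_true(any(f2$rule_id == "S11" & f2$severity == "WARNING"))

  dup <- sdrf_table(tab$columns, tab$cells[c(1, 1, 2), , drop = FALSE])
  f3 <- validate_structure(dup)
  expect_true(any(f3$rule_id == "S12" & f3$row == 2L))

  one_level <- generate_design(design_spec("LABEL_FREE",
                                           factor_levels = "normal"))
  f4 <- validate_structure(one_level)
  expect_true(any(f4$rule_id == "S13" & f4$severity == "INFO"))
})

test_that("the human template enforces disease, organism and control labeling", {
  human <- load_template("human")
  tab <- valid_lf()  # factor levels normal/disease, organism Homo sapiens
  tab <- sdrf_set_column(tab, "characteristics[disease]",
                         c("normal", "normal", "cancer", "cancer"))
  f <- validate_template(tab, human)
  expect_equal(nrow(errors_of(f)), 0L)
  # ancestry is recommended, not required
  expect_true(any(f$rule_id == "H2" & f$severity == "WARNING"))

  lacking <- valid_lf()
  f2 <- validate_template(lacking, human)
  expect_equal(errors_of(f2)$rule_id, "H1")

  mouse <- sdrf_set_column(tab, "characteristics[organism]", "Mus musculus")
  f3 <- validate_template(mouse, human)
  expect_true(all(c("H3") %in% errors_of(f3)$rule_id))

  no_control <- sdrf_set_column(tab, "characteristics[disease]", "cancer")
  f4 <- validate_template(no_control, human)
  expect_true(any(f4$rule_id == "H4" & f4$severity == "INFO"))
})

test_that("the cell-line template elevates severity only when explicit", {
  tab <- valid_lf()
  cl <- load_template("cell-line")
  expect_equal(errors_of(validate_template(tab, cl, explicit = TRUE))$rule_id,
               "C1")
  f <- validate_template(tab, cl, explicit = FALSE)
  expect_true(all(f$severity[f$rule_id == "C1"] == "WARNING"))
  with_line <- sdrf_set_column(tab, "characteristics[cell line]", "HeLa")
  expect_equal(nrow(validate_template(with_line, cl)), 0L)
})

test_that("the default template adds nothing and unknown templates are listed", {
  expect_equal(nrow(validate_template(valid_lf(), load_template("default"))),
               0L)
  expect_error(load_template("nonexistent"), "human")
})

test_that("vocabulary checks flag unknown accessions and label mismatches only", {
  store <- default_cv_store()
  tab <- valid_lf()
  tab <- sdrf_set_column(tab, "comment[modification parameters]",
                         "AC=UNIMOD:35;NT=Oxidation;MT=Variable;TA=M")
  expect_equal(nrow(validate_terms(tab, store)), 0L)

  mismatch <- sdrf_set_column(tab, "comment[modification parameters]",
                              "AC=UNIMOD:35;NT=Phospho;MT=Variable;TA=M")
  f <- validate_terms(mismatch, store)
  expect_true(any(f$rule_id == "V2" & f$severity == "WARNING"))

  unknown <- sdrf_set_column(tab, "comment[modification parameters]",
                             "AC=UNIMOD:424242;NT=Mystery")
  f2 <- validate_terms(unknown, store)
  expect_true(any(f2$rule_id == "V1" & f2$severity == "WARNING"))

  # free text never produces a finding; unknown key/value keys are info
  free <- sdrf_set_column(valid_lf(), "characteristics[organism]",
                          "Homo sapiens")
  expect_equal(nrow(validate_terms(free, store)), 0L)
  custom <- sdrf_set_column(tab, "comment[modification parameters]",
                            "NT=Oxidation;ZZ=custom")
  f3 <- validate_terms(custom, store)
  expect_true(any(f3$rule_id == "V3" & f3$severity == "INFO"))
})

test_that("the aggregate report counts findings and orders deterministically", {
  tab <- valid_tmt()
  rep1 <- validate(tab)
  expect_true(rep1$valid)
  expect_equal(rep1$counts[["ERROR"]], 0L)
  expect_equal(sum(rep1$counts), nrow(rep1$findings))
  rep2 <- validate(tab)
  expect_identical(format_report(rep1), format_report(rep2))
  expect_identical(rep1$findings, rep2$findings)

  empty <- sdrf_table()
  rep_empty <- validate(empty)
  expect_false(rep_empty$valid)
  expect_true(all(c("S1", "S2", "S3", "S4") %in%
                    rep_empty$findings$rule_id))

  js <- jsonlite::fromJSON(report_to_json(rep_empty))
  expect_false(js$valid)
  expect_equal(nrow(js$findings), nrow(rep_empty$findings))
})

test_that("deleting any one required column strictly increases the error count", {
  set.seed(7)
  required <- c("characteristics[organism]", "characteristics[organism part]",
                "characteristics[biological replicate]",
                "comment[fraction identifier]", "comment[technical replicate]",
                "comment[data file]", "comment[label]", "source name",
                "assay name")
  for (i in seq_len(10L)) {
    tab <- generate_design(random_design_spec(max_dim = 3L))
    base_errors <- nrow(errors_of(validate_structure(tab)))
    expect_equal(base_errors, 0L)
    for (col in required) {
      thinned <- sdrf_drop_column(tab, col)
      expect_gt(nrow(errors_of(validate_structure(thinned))), base_errors)
    }
  }
})
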