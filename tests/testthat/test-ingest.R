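test_that("RTstruct ROI names are extracted in order, for both transfer syntaxes", {
  d <- dicom_fixture_dir()
  for (f in c("rs_explicit.dcm", "rs_implicit.dcm")) {
    recs <- read_rtstruct_names(file.path(d, f))
    expect_equal(recs$raw_name, c("Niere li", "PTV"))
    expect_equal(recs$roi_number, 1:2)
    expect_equal(recs$patient_id, rep("PAT001", 2))
  }
})

test_that("RTstruct edge cases raise informative errors or empty results", {
  d <- dicom_fixture_dir()
  expect_equal(nrow(read_rtstruct_names(file.path(d, "rs_empty.dcm"))), 0)
  expect_error(
    read_rtstruct_names(file.path(d, "ct.dcm")),
    "ct.dcm",
    class = "rtnomen_no_structure_set"
  )
  not_dicom <- tempfile()
  writeLines("raw_name\nHeart", not_dicom)
  expect_error(read_rtstruct_names(not_dicom), class = "rtnomen_not_dicom")
  expect_error(read_rtstruct_names(tempfile()), class = "rtnomen_missing_file")
})

test_that("default exclusion rules drop targets and auxiliary structures with tags", {
  recs <- tibble::tibble(raw_name = c("Niere bds", "PTV56", "Couch", "GTVp", "OpticNrv_L"))
  parts <- filter_structures(recs)
  expect_setequal(parts$kept$raw_name, c("Niere bds", "OpticNrv_L"))
  expect_equal(nrow(parts$excluded), 3)
  expect_equal(
    parts$excluded$rule_tag[match(c("PTV56", "GTVp", "Couch"), parts$excluded$raw_name)],
    c("target", "target", "aux")
  )

  # empty rule set keeps everything; malformed patterns name the rule
  all_kept <- filter_structures(recs, rules = character())
  expect_equal(nrow(all_kept$kept), nrow(recs))
  expect_equal(nrow(all_kept$excluded), 0)
  expect_error(
    filter_structures(recs, rules = c(bad = "(unclosed")),
    "bad",
    class = "rtnomen_rule_error"
  )
})

test_that("filtering partitions exhaustively and disjointly on random corpora", {
  lex <- test_lexicon()
  withr::with_seed(11, {
    for (rep in 1:10) {
      pool <- c(
        sample(lex$entries$standard_name, 20),
        "PTV boost", "CTV56", "Couch", "Hilfsvolumen", "hulpstructuur", "opt shell"
      )
      recs <- tibble::tibble(raw_name = sample(pool, 60, replace = TRUE))
      parts <- filter_structures(recs)
      expect_equal(nrow(parts$kept) + nrow(parts$excluded), nrow(recs))
      expect_length(intersect(parts$kept$raw_name, parts$excluded$raw_name), 0)
      expect_false(any(is.na(parts$excluded$rule_tag)))
    }
  })
})

test_that("deduplication counts multiplicities and conserves records", {
  out <- deduplicate(tibble::tibble(raw_name = c("Herz", "Herz", "Heart")))
  expect_equal(out$raw_name, c("Herz", "Heart"))
  expect_equal(out$multiplicity, c(2L, 1L))

  expect_equal(nrow(deduplicate(tibble::tibble(raw_name = character()))), 0)

  withr::with_seed(7, {
    recs <- tibble::tibble(
      raw_name = c(
        c("Herz", "HERZ", "Heart", "hart", "Niere li", "Milz"),
        sample(c("Herz", "HERZ", "Heart", "hart", "Niere li", "Milz"),
          28,
          replace = TRUE
        )
      ),
      center_id = sample(c("A", "B", "C"), 34, replace = TRUE)
    )
  })
  uniq <- deduplicate(recs)
  expect_equal(sum(uniq$multiplicity), 34)
  # case-sensitive by default: Herz and HERZ stay distinct
  expect_true(all(c("Herz", "HERZ") %in% uniq$raw_name))
  # sorted by descending multiplicity then name
  expect_true(all(diff(uniq$multiplicity) <= 0))
  # case-insensitive switch merges them
  uniq_ci <- deduplicate(recs, case_sensitive = FALSE)
  expect_lt(nrow(uniq_ci), nrow(uniq))
  expect_equal(sum(uniq_ci$multiplicity), 34)
})

test_that("filter-then-deduplicate agrees with deduplicate-then-filter", {
  withr::with_seed(23, {
    lex <- test_lexicon()
    for (rep in 1:10) {
      pool <- c(sample(lex$entries$standard_name, 15), "PTV1", "GTV", "Couch", "Bolus 5mm")
      recs <- tibble::tibble(raw_name = sample(pool, 50, replace = TRUE))
      a <- deduplicate(filter_structures(recs)$kept)
      b <- filter_structures(deduplicate(recs))$kept
      expect_setequal(a$raw_name, b$raw_name)
      expect_equal(
        a$multiplicity[order(a$raw_name)],
        b$multiplicity[order(b$raw_name)]
      )
    }
  })
})

test_that("structure tables round-trip through the delimited dialect", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(raw_name = c("Niere li", "Herz"), center_id = "C"),
    path
  )
  df <- read_structure_table(path)
  expect_equal(df$raw_name, c("Niere li", "Herz"))
  expect_true(all(c("patient_id", "language_hint", "ground_truth") %in% names(df)))
  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = "x"), bad)
  expect_error(read_structure_table(bad), class = "rtnomen_table_format")
})
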