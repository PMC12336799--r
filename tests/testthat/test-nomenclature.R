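test_that("the bundled lexicon loads, is sizeable, and satisfies its invariants", {
  lex <- test_lexicon()
  expect_s3_class(lex, "tg263_lexicon")
  expect_gte(nrow(lex$entries), 100)
  expect_true("SpinalCord_Cerv" %in% lex$entries$standard_name)
  # every name referenced by the error-taxonomy worked examples is covered
  expect_true(all(
    c(
      "SpinalCord", "Kidney_L", "Kidneys", "Pharynx", "Musc_Constrict",
      "Sphincter_Anal", "Glnd_Lacrimal_L"
    ) %in% lex$entries$standard_name
  ))
  expect_false(any(duplicated(lex$entries$standard_name)))
  # one normalized synonym never points at two concepts
  amb <- lex$synonyms %>%
    dplyr::distinct(term_norm, concept_id) %>%
    dplyr::count(term_norm) %>%
    dplyr::filter(n > 1)
  expect_equal(nrow(amb), 0)
  # all three languages are represented
  expect_setequal(unique(lex$synonyms$lang), c("en", "de", "nl"))
})

test_that("lexicon loading rejects malformed files with the offender named", {
  empty <- write_lexicon_file(lexicon_header())
  expect_equal(nrow(load_lexicon(empty)$entries), 0)

  dup <- lexicon_header() %>%
    dplyr::bind_rows(tibble::tibble(
      standard_name = c("Kidney", "Kidney"), concept_id = "kidney",
      category = "organ", laterality = "none", spatial_qualifier = NA_character_,
      plurality = "singular", synonyms = c("en:kidney", "en:renal")
    ))
  expect_error(
    load_lexicon(write_lexicon_file(dup)),
    "Kidney",
    class = "rtnomen_duplicate_name"
  )

  clash <- lexicon_header() %>%
    dplyr::bind_rows(tibble::tibble(
      standard_name = c("Kidney", "Liver"), concept_id = c("kidney", "liver"),
      category = "organ", laterality = "none", spatial_qualifier = NA_character_,
      plurality = "singular", synonyms = c("en:organ x", "en:organ x")
    ))
  expect_error(
    load_lexicon(write_lexicon_file(clash)),
    "organ x",
    class = "rtnomen_ambiguous_synonym"
  )

  expect_error(load_lexicon(tempfile()), class = "rtnomen_missing_file")
})

test_that("parse_name decomposes names into concept, laterality, qualifier, plurality", {
  lex <- test_lexicon()
  p <- parse_name(
    c("Glnd_Lacrimal_L", "SpinalCord", "SpinalCord_Cerv", "Niere bds"),
    lex
  )
  expect_equal(p$concept_tokens[[1]], c("Glnd", "Lacrimal"))
  expect_equal(p$laterality, c("left", "none", "none", "none"))
  expect_equal(p$spatial_qualifier, c(NA, NA, "Cerv", NA))
  expect_equal(p$plurality, c("singular", "singular", "singular", "plural"))
  # SpinalCord and SpinalCord_Cerv share concept tokens and concept
  expect_equal(p$concept_tokens[[2]], p$concept_tokens[[3]])
  expect_equal(p$concept_id[2], p$concept_id[3])
  expect_error(parse_name("", lex), class = "rtnomen_invalid_input")
  # deterministic
  expect_identical(p, parse_name(
    c("Glnd_Lacrimal_L", "SpinalCord", "SpinalCord_Cerv", "Niere bds"), lex
  ))
})

test_that("every valid TG-263 name round-trips through parse and compose", {
  lex <- test_lexicon()
  for (nm in lex$entries$standard_name) {
    p <- parse_name(nm, lex)
    expect_identical(compose_name(p), nm)
    expect_identical(parse_name(compose_name(p), lex), p)
  }
})

test_that("parse_name recovers the declared laterality of every sided entry", {
  lex <- test_lexicon()
  sided <- lex$entries[lex$entries$laterality %in% c("left", "right"), ]
  p <- parse_name(sided$standard_name, lex)
  expect_equal(p$laterality, sided$laterality)
  expect_true(all(is_valid_tg263(sided$standard_name, lex)))
})

test_that("same_concept behaves as an equivalence relation and flags unresolvables", {
  lex <- test_lexicon()
  expect_false(same_concept("Pharynx", "Musc_Constrict", lex))
  expect_true(same_concept("Kidney", "Kidney", lex))
  expect_true(same_concept("Lacrimal_Gland_L", "Glnd_Lacrimal_L", lex))
  expect_true(is.na(same_concept("zzzz", "Kidney", lex)))

  # reflexivity and symmetry over a mixed sample of names and synonyms
  sample_names <- c(
    lex$entries$standard_name[seq(1, 101, by = 10)],
    "Niere li", "traanklier", "myelum"
  )
  expect_true(all(same_concept(sample_names, sample_names, lex)))
  for (a in sample_names[1:5]) {
    for (b in sample_names[6:10]) {
      expect_identical(same_concept(a, b, lex), same_concept(b, a, lex))
    }
  }
})

test_that("TG-263 validity is exact, case-sensitive membership", {
  lex <- test_lexicon()
  expect_true(is_valid_tg263("Kidneys", lex))
  expect_true(is_valid_tg263(" SpinalCord ", lex)) # trimmed
  expect_false(is_valid_tg263("", lex))
  expect_false(is_valid_tg263("kidneys", lex))
  expect_false(is_valid_tg263("Lacrimal_Gland_L", lex)) # synonym, not standard
})
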