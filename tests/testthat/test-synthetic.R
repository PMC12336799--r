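test_that("corpus generation is fully reproducible from its seed", {
  lex <- test_lexicon()
  cfg <- corruption_config(seed = 99)
  c1 <- generate_corpus(lex, 100, cfg)
  c2 <- generate_corpus(lex, 100, cfg)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_corpus(lex, 100, corruption_config(seed = 100))))
  expect_equal(nrow(generate_corpus(lex, 0, cfg)), 0)
})

test_that("a no-op corpus reproduces standard spellings verbatim", {
  lex <- test_lexicon()
  cfg <- corruption_config(
    op_rates = c(
      none = 1, translate = 0, abbreviate = 0, lateral_notation = 0,
      plurality = 0, misspell = 0, case_sep = 0
    ),
    seed = 12
  )
  corpus <- generate_corpus(lex, 80, cfg)
  expect_true(all(corpus$raw_name == corpus$ground_truth))
  expect_true(all(is_valid_tg263(corpus$raw_name, lex)))
})

test_that("corrupted corpora carry exact provenance and conserve multiplicities", {
  lex <- test_lexicon()
  corpus <- generate_corpus(lex, 150, corruption_config(seed = 21))
  expect_true(all(is_valid_tg263(corpus$ground_truth, lex)))
  expect_true(all(corpus$op_sampled %in% names(corruption_config()$op_rates)))
  items <- corpus[!duplicated(corpus$item_id), ]
  expect_equal(nrow(corpus), sum(items$multiplicity))
  # a raw spelling never carries two different truths
  conflicts <- corpus %>%
    dplyr::distinct(raw_name, ground_truth) %>%
    dplyr::count(raw_name) %>%
    dplyr::filter(n > 1)
  expect_equal(nrow(conflicts), 0)
  # language/center consistency: German names come from center C
  expect_true(all(corpus$center_id[corpus$language_hint == "de"] == "C"))
  expect_true(all(corpus$center_id[corpus$language_hint == "nl"] %in% c("A", "B")))
})

test_that("realized operator frequencies converge to the configured rates", {
  lex <- test_lexicon()
  cfg <- corruption_config(seed = 10)
  corpus <- generate_corpus(lex, 2000, cfg)
  items <- corpus[!duplicated(corpus$item_id), ]
  obs <- table(factor(items$op_sampled, levels = names(cfg$op_rates)))
  gof <- stats::chisq.test(as.vector(obs), p = cfg$op_rates)
  expect_gt(gof$p.value, 0.01)
})

test_that("the German translate chain can produce abbreviated-laterality spellings", {
  lex <- test_lexicon()
  # sweep seeds: Glnd_Lacrimal_L rendered in German with an abbreviated
  # laterality marker must appear (e.g. "Traenendruese li.")
  seen <- character()
  cfg_base <- corruption_config(
    language_mix = c(en = 0, de = 1, nl = 0),
    op_rates = c(
      none = 0, translate = 1, abbreviate = 0, lateral_notation = 0,
      plurality = 0, misspell = 0, case_sep = 0
    ),
    seed = 1
  )
  for (s in 1:12) {
    cfg <- cfg_base
    cfg$seed <- s
    corpus <- generate_corpus(lex, 120, cfg)
    seen <- c(seen, corpus$raw_name[corpus$ground_truth == "Glnd_Lacrimal_L"])
  }
  expect_true(any(grepl("^Traenendruese li|^Tränendrüse li", seen)))
  # and the mock backend inverts those spellings
  hits <- unique(seen[grepl("(?i)traenendruese", seen, perl = TRUE)])
  pred <- rename_batch(hits, backend_mock(lex))
  expect_true(all(pred$predicted_name == "Glnd_Lacrimal_L"))
})

test_that("the simulated backend realizes its programmed error rate", {
  lex <- test_lexicon()
  withr::with_seed(41, {
    items <- tibble::tibble(
      raw_name = sprintf("item%05d", 1:10000),
      ground_truth = sample(lex$entries$standard_name, 10000, replace = TRUE)
    )
  })
  eps <- 0.2
  sb <- backend_simulated(items, lex, simulated_backend_config(error_rate = eps, seed = 6))
  measured <- mean(sb$items$wrong)
  se <- sqrt(eps * (1 - eps) / nrow(items))
  expect_lt(abs(measured - eps), 3 * se)
  # modal answers of correct items are their ground truths
  ok <- !sb$items$wrong
  expect_true(all(sb$items$modal[ok] == sb$items$ground_truth[ok]))
})

test_that("category-targeted injections are recovered by the error classifier", {
  lex <- test_lexicon()
  pools <- list(
    LATERALITY_OR_LOCALITY = laterality_pool(lex),
    PLURALITY = plurality_pool(lex),
    NO_MATCH = lex$entries$standard_name,
    MISSPELLING = lex$entries$standard_name,
    WRONG_OAR = lex$entries$standard_name
  )
  for (cat in names(pools)) {
    withr::with_seed(53, {
      items <- tibble::tibble(
        raw_name = sprintf("%s_%03d", tolower(cat), 1:50),
        ground_truth = sample(pools[[cat]], 50, replace = TRUE)
      )
    })
    mix <- setNames(1, cat)
    sb <- backend_simulated(items, lex, simulated_backend_config(
      error_rate = 1, category_mix = mix, seed = 7
    ))
    tab <- sb$items
    expect_true(all(tab$category == cat), label = paste("injected", cat))
    got <- classify_error(tab$modal, tab$ground_truth, lex)
    expect_true(all(got == cat), label = paste("recovered", cat))
  }
})

test_that("degenerate simulated backends behave as programmed", {
  lex <- test_lexicon()
  items <- tibble::tibble(
    raw_name = paste0("n", 1:30),
    ground_truth = rep(c("Heart", "Liver", "Spleen"), 10)
  )
  # perfect backend
  perfect <- backend_simulated(items, lex, simulated_backend_config(error_rate = 0, seed = 1))
  pred <- rename_batch(items, perfect)
  sc <- score_predictions(
    pred %>% dplyr::left_join(items, by = "raw_name"), lex
  )
  expect_equal(accuracy_report(sc)$overall$unique_accuracy, 1)

  # everything no-match
  nm <- backend_simulated(items, lex, simulated_backend_config(
    error_rate = 1, category_mix = c(NO_MATCH = 1), seed = 1
  ))
  sc2 <- score_predictions(
    rename_batch(items, nm) %>% dplyr::left_join(items, by = "raw_name"), lex
  )
  hist <- accuracy_report(sc2)$error_histogram
  expect_equal(hist$count[hist$error_type == "NO_MATCH"], 30)
  expect_equal(sum(hist$count), 30)
})
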