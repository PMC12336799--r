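test_that("shannon_entropy matches direct evaluation of the defining formula", {
  expect_equal(shannon_entropy(rep("SpinalCord", 10)), 0)
  expect_equal(shannon_entropy(c(rep("A", 5), rep("B", 5))), log(2))
  # counts 6/3/1 of 10, reference value evaluated directly
  expect_equal(
    shannon_entropy(c(rep("A", 6), rep("B", 3), "C")),
    -(0.6 * log(0.6) + 0.3 * log(0.3) + 0.1 * log(0.1)),
    tolerance = 1e-15
  )
  # invariance under permutation and relabeling
  withr::with_seed(3, {
    labs <- sample(c("x", "y", "z", no_match()), 40, replace = TRUE)
    expect_equal(shannon_entropy(labs), shannon_entropy(sample(labs)))
    relabeled <- setNames(c("L1", "L2", "L3", "L4"), c("x", "y", "z", no_match()))[labs]
    expect_equal(shannon_entropy(labs), shannon_entropy(relabeled))
  })
  expect_error(shannon_entropy(character()), class = "rtnomen_invalid_input")
})

test_that("entropy respects its bounds with exact equality cases", {
  withr::with_seed(17, {
    for (i in 1:200) {
      n_lab <- sample(1:6, 1)
      labs <- sample(letters[1:n_lab], sample(1:30, 1), replace = TRUE)
      h <- shannon_entropy(labs)
      n_distinct <- length(unique(labs))
      expect_gte(h, 0)
      expect_lte(h, log(max(n_distinct, 1)) + 1e-12)
      expect_identical(h == 0, n_distinct == 1)
    }
  })
  # uniform distribution attains the upper bound exactly
  expect_equal(shannon_entropy(letters[1:5]), log(5))
})

test_that("phi_correlation equals brute-force Pearson on expanded vectors", {
  expect_equal(phi_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0))$phi, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_equal(phi_correlation(x, x)$phi, 1)
  # a=3 b=1 c=1 d=5 against the expanded-vector oracle
  expect_equal(phi_correlation(
    c(rep(1, 4), rep(0, 6)),
    c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  )$phi, phi_oracle(3, 1, 1, 5), tolerance = 1e-12)

  withr::with_seed(29, {
    for (i in 1:200) {
      cells <- rmultinom(1, sample(8:60, 1), prob = runif(4, 0.05, 1))[, 1]
      assoc <- phi_correlation(
        rep(c(1, 1, 0, 0), cells),
        rep(c(1, 0, 1, 0), cells)
      )
      if (assoc$degenerate) {
        expect_true(is.na(assoc$phi))
      } else {
        expect_equal(assoc$phi, phi_oracle(cells[1], cells[2], cells[3], cells[4]),
          tolerance = 1e-12
        )
        expect_lte(abs(assoc$phi), 1)
      }
    }
  })
})

test_that("degenerate margins are flagged, never silently zero", {
  assoc <- phi_correlation(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_true(assoc$degenerate)
  expect_true(is.na(assoc$phi))
  expect_error(phi_correlation(c(1, 0), c(1, 0, 1)), class = "rtnomen_invalid_input")
  expect_error(phi_correlation(1, 1), class = "rtnomen_invalid_input")
})

test_that("sampling honours the seed contract and warns on temperature 0", {
  lex <- test_lexicon()
  items <- tibble::tibble(raw_name = "x1", ground_truth = "Heart")
  sb <- backend_simulated(items, lex, simulated_backend_config(
    error_rate = 1, variability = 0.7, seed = 4
  ))
  s1 <- sample_predictions("x1", sb, k = 10, backend_config(temperature = 1, seed = 99))
  s2 <- sample_predictions("x1", sb, k = 10, backend_config(temperature = 1, seed = 99))
  expect_identical(s1$label, s2$label)
  expect_equal(nrow(s1), 10)

  expect_warning(
    s0 <- sample_predictions("x1", sb, k = 5, backend_config(temperature = 0)),
    "deterministic"
  )
  expect_equal(length(unique(s0$label)), 1)
  expect_equal(nrow(sample_predictions("x1", sb, k = 1, backend_config(temperature = 1, seed = 1))), 1)
})

test_that("a deterministic sampler flags nothing and yields perfect specificity", {
  lex <- test_lexicon()
  items <- tibble::tibble(
    raw_name = paste0("it", 1:10),
    ground_truth = sample(lex$entries$standard_name, 10)
  )
  sb <- backend_simulated(items, lex, simulated_backend_config(
    error_rate = 0.5, variability = 0, variability_correct = 0, seed = 8
  ))
  prof <- uncertainty_profile(items$raw_name, sb,
    k = 6,
    config = backend_config(temperature = 1, top_p = 0.95, seed = 3)
  )
  expect_false(any(prof$flagged))
  expect_true(all(prof$entropy == 0))
  m <- entropy_error_metrics(prof %>% dplyr::mutate(correct = !sb$items$wrong))
  expect_equal(m$specificity, 1)
  expect_equal(m$sensitivity, 0)
})

test_that("entropy metrics handle the perfect-separation and degenerate cases", {
  perfect <- tibble::tibble(
    correct = c(rep(TRUE, 5), rep(FALSE, 5)),
    entropy = c(rep(0, 5), rep(0.5, 5))
  )
  m <- entropy_error_metrics(perfect)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$phi$phi, 1)

  all_zero <- tibble::tibble(correct = c(TRUE, FALSE), entropy = c(0, 0))
  m0 <- entropy_error_metrics(all_zero)
  expect_equal(m0$specificity, 1)
  expect_equal(m0$sensitivity, 0)
  expect_true(m0$phi$degenerate)

  expect_error(entropy_error_metrics(perfect[0, ]), class = "rtnomen_empty_input")
})

test_that("confidence coding follows low/medium=1, high=0 against errors", {
  recs <- tibble::tibble(
    confidence = c("low", "medium", "high", "high", "missing", "high"),
    correct = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  assoc <- confidence_error_correlation(recs)
  expect_equal(assoc$phi, 1) # perfect agreement incl. missing -> low
  const <- tibble::tibble(confidence = rep("high", 4), correct = c(TRUE, FALSE, TRUE, FALSE))
  expect_true(confidence_error_correlation(const)$degenerate)

  # programmed joint distribution against the direct Pearson oracle
  withr::with_seed(31, {
    conf <- sample(c("low", "medium", "high"), 200, replace = TRUE)
    corr <- runif(200) < ifelse(conf == "high", 0.9, 0.3)
  })
  assoc2 <- confidence_error_correlation(tibble::tibble(confidence = conf, correct = corr))
  oracle <- stats::cor(as.integer(conf %in% c("low", "medium")), as.integer(!corr))
  expect_equal(assoc2$phi, oracle, tolerance = 1e-12)
})
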