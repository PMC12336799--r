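#' Backend configuration
#'
#' Sampling and transport parameters shared by all renaming backends.
#' `temperature = 0` activates the deterministic contract: identical input
#' must yield an identical prediction on every call. With `temperature > 0`
#' backends sample among their top candidates, restricted to the smallest
#' candidate set whose cumulative probability exceeds `top_p`; `seed` makes
#' that sampling reproducible.
#'
#' @param temperature non-negative real; 0 = deterministic.
#' @param top_p real in (0, 1]; nucleus-sampling mass.
#' @param seed optional integer seed used by [rename_batch()] and
#'   [sample_predictions()] to isolate backend randomness.
#' @param retries bounded number of retries for remote transport failures.
#' @return a `backend_config` list.
#' @examples
#' backend_config()
#' backend_config(temperature = 1, top_p = 0.95, seed = 7)
#' @export
backend_config <- function(temperature = 0, top_p = 0.95, seed = NULL, retries = 2) {
  stopifnot(
    is.numeric(temperature), length(temperature) == 1, temperature >= 0,
    is.numeric(top_p), length(top_p) == 1, top_p > 0, top_p <= 1,
    is.null(seed) || (is.numeric(seed) && length(seed) == 1)
  )
  structure(
    list(
      temperature = temperature, top_p = top_p,
      seed = if (!is.null(seed)) as.integer(seed), retries = as.integer(retries)
    ),
    class = "backend_config"
  )
}

new_prediction <- function(raw_name, predicted_name, confidence, raw_response,
                           backend_id, parse_ok = TRUE, error = NA_character_) {
  tibble(
    raw_name = raw_name,
    predicted_name = predicted_name,
    confidence = confidence,
    parse_ok = parse_ok,
    raw_response = raw_response,
    backend_id = backend_id,
    error = error
  )
}

#' Deterministic multilingual mock renaming backend
#'
#' A fully offline stand-in for an LLM backend, usable as the default engine
#' and as the test double for the whole pipeline. The renaming cascade is:
#' normalize (lowercase, strip punctuation and digits), detect laterality /
#' qualifier / plurality markers (including abbreviations such as `li`, `re`,
#' `bds`), translate the residual tokens through the lexicon's multilingual
#' synonym table, and — when no exact synonym matches — rank candidate
#' concepts by bounded normalized edit distance. The best candidate is
#' composed with the detected markers into a standard name; scores below
#' `threshold` yield [no_match()].
#'
#' Confidence is `"high"` for exact standard-name or synonym hits, `"medium"`
#' for clear fuzzy hits and `"low"` near the threshold. At `temperature = 0`
#' the backend is fully deterministic; with `temperature > 0` it samples
#' among the top-scoring candidates with probability proportional to an
#' exponential of their score, restricted to the top-`top_p` mass.
#'
#' @param lexicon a [load_lexicon()] object.
#' @param threshold normalized-similarity cutoff below which the backend
#'   answers no match. The default (0.72) is chosen so that clean synthetic
#'   names pass while random strings fail; it is configuration, not a
#'   hard-coded constant.
#' @param fuzzy_margin width of the "low confidence" band above `threshold`.
#' @param n_candidates number of candidate concepts kept for sampling mode.
#' @return an `rtnomen_backend` object for use with [rename_batch()].
#' @examples
#' backend <- backend_mock(load_lexicon())
#' rename_one("Niere bds", backend)
#' @export
backend_mock <- function(lexicon, threshold = 0.72, fuzzy_margin = 0.1,
                         n_candidates = 8) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  structure(
    list(
      id = "mock",
      lexicon = lexicon,
      threshold = threshold,
      fuzzy_margin = fuzzy_margin,
      n_candidates = n_candidates
    ),
    class = c("rtnomen_backend_mock", "rtnomen_backend")
  )
}

# score candidate standard names for one input
mock_candidates <- function(backend, name) {
  lexicon <- backend$lexicon
  entries <- lexicon$entries
  nm <- trimws(name)

  if (nm %in% entries$standard_name) {
    return(tibble(standard_name = nm, score = 1))
  }
  parsed <- resolve_one(nm, lexicon)
  lat <- parsed$laterality
  qual <- parsed$spatial_qualifier
  plur <- parsed$plurality
  if (parsed$resolved && !is.na(parsed$standard_name)) {
    exact <- tibble(standard_name = parsed$standard_name, score = 1)
  } else {
    exact <- NULL
  }

  # fuzzy stage: compare the residual phrase against every synonym term and
  # normalized standard name, keep the best similarity per concept
  phrase <- normalize_name(paste(parsed$concept_tokens[[1]], collapse = " "))
  if (!nzchar(phrase)) phrase <- normalize_name(nm)
  terms <- bind_rows(
    lexicon$synonyms %>% select("concept_id", term = "term_norm"),
    tibble(concept_id = entries$concept_id, term = normalize_name(entries$standard_name))
  ) %>% distinct()
  d <- as.vector(adist(phrase, terms$term))
  sim <- 1 - d / pmax(nchar(phrase), nchar(terms$term))
  fuzzy <- tibble(concept_id = terms$concept_id, sim = sim) %>%
    group_by(.data$concept_id) %>%
    summarise(score = max(.data$sim), .groups = "drop") %>%
    arrange(desc(.data$score)) %>%
    head(backend$n_candidates)
  fuzzy$standard_name <- purrr::map_chr(fuzzy$concept_id, function(cid) {
    select_entry(entries[entries$concept_id == cid, ], lat, qual, plur)
  })
  out <- bind_rows(exact, fuzzy %>% select("standard_name", "score")) %>%
    filter(!is.na(.data$standard_name)) %>%
    group_by(.data$standard_name) %>%
    summarise(score = max(.data$score), .groups = "drop") %>%
    arrange(desc(.data$score))
  out
}

mock_confidence <- function(backend, score) {
  if (score >= 1) {
    "high"
  } else if (score >= backend$threshold + backend$fuzzy_margin) {
    "medium"
  } else {
    "low"
  }
}

predict_backend <- function(backend, name, config) {
  UseMethod("predict_backend")
}

#' @export
predict_backend.rtnomen_backend_mock <- function(backend, name, config) {
  cand <- mock_candidates(backend, name)
  if (nrow(cand) == 0 || max(cand$score) < backend$threshold) {
    pred <- no_match()
    conf <- "low"
  } else {
    keep <- cand %>% filter(.data$score >= backend$threshold)
    if (config$temperature > 0 && nrow(keep) > 1) {
      pick <- sample_top_p(keep$score, config$temperature, config$top_p)
    } else {
      pick <- 1L
    }
    pred <- keep$standard_name[pick]
    conf <- mock_confidence(backend, keep$score[pick])
  }
  new_prediction(
    raw_name = name, predicted_name = pred, confidence = conf,
    raw_response = render_response(pred, conf), backend_id = backend$id
  )
}

# nucleus sampling over candidate scores (descending order assumed):
# exponential weights sharpened by 1/temperature, truncated to the smallest
# prefix with cumulative mass > top_p. As top_p -> 0 this degenerates to the
# deterministic argmax.
sample_top_p <- function(scores, temperature, top_p, sharpness = 8) {
  w <- exp((scores - max(scores)) * sharpness / temperature)
  p <- w / sum(w)
  k <- which(cumsum(p) >= top_p)[1]
  if (is.na(k)) k <- length(p)
  p <- p[seq_len(k)] / sum(p[seq_len(k)])
  sample.int(k, 1, prob = p)
}

#' Rename a single structure name
#'
#' Convenience wrapper around a backend for one name; see [rename_batch()]
#' for the batch contract.
#'
#' @param name a single raw structure name.
#' @param backend an `rtnomen_backend` (e.g. [backend_mock()]).
#' @param config a [backend_config()].
#' @return a one-row prediction tibble.
#' @export
rename_one <- function(name, backend, config = backend_config()) {
  rename_batch(name, backend, config)
}

#' Rename a batch of structure names through a backend
#'
#' Applies the backend to each name in order. Per-item failures (transport
#' errors, unparseable replies) are recorded in the `error` / `parse_ok`
#' columns and never abort the run; raw responses are always retained. When
#' `config$seed` is set, all backend randomness is drawn from an isolated
#' RNG stream, so repeated calls reproduce the same predictions.
#'
#' @param names character vector of raw names, or a data frame with a
#'   `raw_name` column (e.g. the output of [deduplicate()]).
#' @param backend an `rtnomen_backend`.
#' @param config a [backend_config()].
#' @return a tibble with one row per input name: `raw_name`,
#'   `predicted_name`, `confidence`, `parse_ok`, `raw_response`,
#'   `backend_id`, `error`.
#' @examples
#' backend <- backend_mock(load_lexicon())
#' rename_batch(c("Niere bds", "myelum", "zzzz"), backend)
#' @export
rename_batch <- function(names, backend, config = backend_config()) {
  stopifnot(inherits(backend, "rtnomen_backend"))
  if (is.data.frame(names)) names <- names$raw_name
  names <- as.character(names)
  run <- function() {
    purrr::map(names, function(nm) {
      tryCatch(
        predict_backend(backend, nm, config),
        error = function(e) {
          new_prediction(
            raw_name = nm, predicted_name = NA_character_,
            confidence = "missing", raw_response = NA_character_,
            backend_id = backend$id, parse_ok = FALSE,
            error = conditionMessage(e)
          )
        }
      )
    })
  }
  out <- if (!is.null(config$seed)) {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
  bind_rows(out)
}
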