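# Synthetic multilingual corpora and a programmable simulated backend.
#
# The generator emulates the statistical shape of a multi-center clinical
# structure-name corpus: center-specific names in English, German and Dutch
# derived from TG-263 names by translation, abbreviation, laterality-notation
# changes, plurality changes, misspellings and case/separator changes, with a
# heavy-tailed duplicate-multiplicity distribution (so the full corpus is
# much larger than its unique-name view).

#' Corruption configuration for the synthetic corpus generator
#'
#' @param language_mix named probabilities over `en`, `de`, `nl` (sums to 1).
#' @param op_rates named probabilities over the corruption operators
#'   `none`, `translate`, `abbreviate`, `lateral_notation`, `plurality`,
#'   `misspell`, `case_sep` (sums to 1). One operator is drawn per unique
#'   name; `translate` renders laterality in the target language and is the
#'   base for `abbreviate` and `misspell`.
#' @param mult_alpha tail exponent of the discrete power-law multiplicity
#'   distribution (P(m) ~ m^-alpha); smaller = heavier tail.
#' @param mult_max cap on the multiplicity of a single unique name.
#' @param misspell_edits maximum number of random character edits applied by
#'   the `misspell` operator (the count is drawn uniformly from
#'   `1:misspell_edits`).
#' @param seed integer; fully determines the generated corpus.
#' @return a `corruption_config` list.
#' @export
corruption_config <- function(language_mix = c(en = 0.3, de = 0.35, nl = 0.35),
                              op_rates = c(
                                none = 0.2, translate = 0.3, abbreviate = 0.15,
                                lateral_notation = 0.1, plurality = 0.05,
                                misspell = 0.1, case_sep = 0.1
                              ),
                              mult_alpha = 2.2, mult_max = 200,
                              misspell_edits = 2, seed = 1) {
  stopifnot(
    abs(sum(language_mix) - 1) < 1e-8,
    all(names(language_mix) %in% c("en", "de", "nl")),
    abs(sum(op_rates) - 1) < 1e-8,
    all(names(op_rates) %in% c(
      "none", "translate", "abbreviate", "lateral_notation",
      "plurality", "misspell", "case_sep"
    )),
    mult_alpha > 1, mult_max >= 1
  )
  structure(
    list(
      language_mix = language_mix, op_rates = op_rates,
      mult_alpha = mult_alpha, mult_max = mult_max,
      misspell_edits = misspell_edits, seed = as.integer(seed)
    ),
    class = "corruption_config"
  )
}

lateral_words <- function() {
  list(
    en = list(left = c("left", "l", "lt"), right = c("right", "r", "rt"), both = c("both", "bilateral")),
    de = list(left = c("links", "li", "li."), right = c("rechts", "re", "re."), both = c("bds", "bds.", "beidseits")),
    nl = list(left = c("links", "li"), right = c("rechts", "re"), both = c("bds", "beide"))
  )
}

# sample a synonym term of `entry` in language `lang` (falling back to en)
entry_synonym <- function(lexicon, entry, lang) {
  syn <- lexicon$synonyms
  own <- syn[syn$standard_name == entry$standard_name & syn$lang == lang, ]
  if (nrow(own) == 0) {
    own <- syn[syn$standard_name == entry$standard_name & syn$lang == "en", ]
  }
  if (nrow(own) == 0) {
    return(NULL)
  }
  own$term[sample.int(nrow(own), 1)]
}

random_edits <- function(x, n_edits) {
  chars <- strsplit(x, "")[[1]]
  for (i in seq_len(n_edits)) {
    if (length(chars) < 2) break
    pos <- sample.int(length(chars), 1)
    op <- sample(c("sub", "del", "ins", "swap"), 1)
    if (op == "sub") {
      chars[pos] <- sample(letters, 1)
    } else if (op == "del") {
      chars <- chars[-pos]
    } else if (op == "ins") {
      chars <- append(chars, sample(letters, 1), after = pos)
    } else if (pos < length(chars)) {
      chars[c(pos, pos + 1)] <- chars[c(pos + 1, pos)]
    }
  }
  paste(chars, collapse = "")
}

# apply one corruption operator; returns list(raw, op) -- op records the
# realized operator chain (fallbacks included)
corrupt_name <- function(lexicon, entry, lang, op, cfg) {
  lw <- lateral_words()[[lang]]
  lat_suffix <- function(style_pool) {
    if (entry$laterality %in% c("left", "right")) {
      paste0(" ", sample(style_pool[[entry$laterality]], 1))
    } else {
      ""
    }
  }
  translate <- function() {
    base <- entry_synonym(lexicon, entry, lang)
    if (is.null(base)) {
      return(NULL)
    }
    nm <- paste0(base, lat_suffix(lw))
    if (lang == "de") nm <- stringr::str_to_sentence(nm)
    nm
  }
  out <- switch(op,
    none = entry$standard_name,
    case_sep = {
      nm <- gsub("_", " ", entry$standard_name)
      if (runif(1) < 0.5) tolower(nm) else toupper(nm)
    },
    translate = translate(),
    abbreviate = {
      base <- entry_synonym(lexicon, entry, "en")
      if (is.null(base)) {
        NULL
      } else {
        first <- strsplit(base, " ")[[1]][1]
        if (nchar(first) > 8) first <- paste0(substr(first, 1, 6), ".")
        paste0(first, lat_suffix(lw))
      }
    },
    lateral_notation = {
      if (entry$laterality %in% c("left", "right")) {
        stem <- sub("_[LR]$", "", entry$standard_name)
        word <- sample(lateral_words()$en[[entry$laterality]], 1)
        if (runif(1) < 0.5) paste(stem, word) else paste(word, stem)
      } else {
        NULL
      }
    },
    plurality = {
      # plural concept written as singular word + bilateral marker
      if (entry$plurality == "plural") {
        sib <- lexicon$entries[
          lexicon$entries$concept_id == entry$concept_id &
            lexicon$entries$plurality == "singular",
        ]
        if (nrow(sib) > 0) {
          base <- entry_synonym(lexicon, sib[1, ], lang)
          if (!is.null(base)) {
            nm <- paste0(base, " ", sample(lw$both, 1))
            if (lang == "de") nm <- stringr::str_to_sentence(nm)
            nm
          } else {
            NULL
          }
        } else {
          NULL
        }
      } else {
        NULL
      }
    },
    misspell = {
      base <- translate()
      if (is.null(base)) NULL else random_edits(base, sample.int(cfg$misspell_edits, 1))
    }
  )
  if (is.null(out)) {
    # operator not applicable to this entry/language: degrade to translate,
    # then to the identity
    fallback <- translate()
    if (is.null(fallback)) {
      return(list(raw = entry$standard_name, op = paste0(op, ">none")))
    }
    return(list(raw = fallback, op = paste0(op, ">translate")))
  }
  list(raw = out, op = op)
}

# discrete power-law multiplicity: P(m) ~ m^(-alpha), truncated
draw_multiplicity <- function(alpha, max_mult) {
  m <- ceiling(runif(1)^(-1 / (alpha - 1)))
  as.integer(min(m, max_mult))
}

#' Generate a labeled synthetic structure-name corpus
#'
#' Draws `size` corrupted base names from the lexicon under a
#' [corruption_config()] and expands each with a heavy-tailed duplicate
#' multiplicity into individual records, emulating a pooled multi-center
#' corpus (centers are assigned consistently with the record language:
#' Dutch-language names come from centers A/B, German from center C). A raw
#' spelling may be drawn more than once — real corpora repeat names — but
#' never with a conflicting ground truth; [deduplicate()] merges such
#' recurrences, so the unique-name view can be slightly smaller than
#' `size`. Every record stores its true TG-263 name, the sampled operator
#' (`op_sampled`) and the realized operator chain (`op`, fallbacks
#' included), so all downstream accuracy and error metrics have exact
#' references. The corpus is fully reproducible from `config$seed`.
#'
#' @param lexicon a [load_lexicon()] object with synonyms in the requested
#'   languages.
#' @param size number of unique names to generate.
#' @param config a [corruption_config()].
#' @return a tibble of records: `raw_name`, `center_id`, `patient_id`,
#'   `language_hint`, `ground_truth`, `op`, `op_sampled`, `item_id`,
#'   `multiplicity`. `deduplicate()` recovers the unique-name view.
#' @examples
#' corpus <- generate_corpus(load_lexicon(), 20, corruption_config(seed = 7))
#' head(corpus)
#' @export
generate_corpus <- function(lexicon, size, config = corruption_config()) {
  stopifnot(inherits(lexicon, "tg263_lexicon"), size >= 0)
  langs <- names(config$language_mix)
  missing_lang <- setdiff(langs[config$language_mix > 0], unique(lexicon$synonyms$lang))
  if (length(missing_lang) > 0) {
    abort(
      paste0(
        "Lexicon has no synonyms in requested language(s): ",
        paste(missing_lang, collapse = ", ")
      ),
      class = "rtnomen_missing_language"
    )
  }
  withr::with_seed(config$seed, {
    entries <- lexicon$entries
    # raw name -> ground truth; a raw spelling may recur (it then adds to the
    # name's multiplicity), but never with a conflicting truth
    used <- character()
    items <- list()
    attempts <- 0
    while (length(items) < size && attempts < 50 * (size + 1)) {
      attempts <- attempts + 1
      e <- entries[sample.int(nrow(entries), 1), ]
      lang <- sample(langs, 1, prob = config$language_mix)
      op <- sample(names(config$op_rates), 1, prob = config$op_rates)
      res <- corrupt_name(lexicon, e, lang, op, config)
      key <- trimws(res$raw)
      if (!nzchar(key)) next
      if (!is.na(used[key]) && used[key] != e$standard_name) next
      used[key] <- e$standard_name
      op_drawn <- op
      items[[length(items) + 1]] <- tibble(
        raw_name = res$raw,
        language_hint = lang,
        ground_truth = e$standard_name,
        op = res$op,
        op_sampled = op_drawn,
        multiplicity = draw_multiplicity(config$mult_alpha, config$mult_max)
      )
    }
    items <- bind_rows(items)
    if (nrow(items) == 0) {
      return(tibble(
        raw_name = character(), center_id = character(),
        patient_id = character(), language_hint = character(),
        ground_truth = character(), op = character(),
        op_sampled = character(), item_id = integer(), multiplicity = integer()
      ))
    }
    items$item_id <- seq_len(nrow(items))
    items$center_id <- purrr::map_chr(items$language_hint, function(l) {
      switch(l,
        de = "C",
        nl = sample(c("A", "B"), 1),
        en = sample(c("A", "B", "C"), 1)
      )
    })
    records <- items[rep(items$item_id, items$multiplicity), ]
    records$patient_id <- paste0(
      "P", sprintf("%05d", seq_len(nrow(records)))
    )
    records %>%
      select(
        "raw_name", "center_id", "patient_id", "language_hint",
        "ground_truth", "op", "op_sampled", "item_id", "multiplicity"
      )
  })
}

#' Configuration of the simulated backend
#'
#' A programmable test double standing in for a stochastic renaming backend:
#' per item it errs with probability `error_rate` (the error category drawn
#' from `category_mix`), and in sampling mode each inference deviates from
#' the item's modal answer with probability `variability` (wrong items) or
#' `variability_correct` (correct items). Self-reported confidence is low
#' with probability `p_low_given_wrong` / `p_low_given_correct`. All
#' randomness is resolved once, at construction, from `seed`.
#'
#' @param error_rate fraction of items answered incorrectly at
#'   temperature 0.
#' @param category_mix named probabilities over the error categories
#'   `WRONG_OAR`, `LATERALITY_OR_LOCALITY`, `PLURALITY`, `MISSPELLING`,
#'   `NO_MATCH`.
#' @param variability per-inference deviation probability for wrong items in
#'   sampling mode (temperature > 0).
#' @param variability_correct same for correct items (default 0: correct
#'   answers are stable).
#' @param p_low_given_wrong,p_low_given_correct probability of a low
#'   confidence rating for wrong / correct items.
#' @param seed integer seed.
#' @return a `simulated_backend_config` list.
#' @export
simulated_backend_config <- function(error_rate = 0.1,
                                     category_mix = c(
                                       WRONG_OAR = 0.3,
                                       LATERALITY_OR_LOCALITY = 0.25,
                                       PLURALITY = 0.1,
                                       MISSPELLING = 0.15,
                                       NO_MATCH = 0.2
                                     ),
                                     variability = 0.5,
                                     variability_correct = 0,
                                     p_low_given_wrong = 0.8,
                                     p_low_given_correct = 0.05,
                                     seed = 1) {
  stopifnot(
    error_rate >= 0, error_rate <= 1,
    abs(sum(category_mix) - 1) < 1e-8,
    all(names(category_mix) %in% setdiff(error_categories(), "NONE")),
    variability >= 0, variability <= 1,
    variability_correct >= 0, variability_correct <= 1
  )
  structure(
    list(
      error_rate = error_rate, category_mix = category_mix,
      variability = variability, variability_correct = variability_correct,
      p_low_given_wrong = p_low_given_wrong,
      p_low_given_correct = p_low_given_correct,
      seed = as.integer(seed)
    ),
    class = "simulated_backend_config"
  )
}

# construct a wrong prediction of the requested category for a ground truth;
# returns list(prediction, category) with the achieved category (fallbacks
# degrade to WRONG_OAR, then NO_MATCH)
make_wrong_prediction <- function(gt, category, lexicon) {
  entries <- lexicon$entries
  if (is_no_match(gt)) {
    # any concrete name is wrong when the truth is "no TG-263 name"
    pick <- entries$standard_name[sample.int(nrow(entries), 1)]
    return(list(prediction = pick, category = "WRONG_OAR"))
  }
  e <- entries[entries$standard_name == gt, ]
  if (nrow(e) == 0) {
    return(list(prediction = no_match(), category = "NO_MATCH"))
  }
  title_form <- function(term, laterality = "none") {
    parts <- stringr::str_to_title(strsplit(term, " ")[[1]])
    nm <- paste(parts, collapse = "_")
    if (laterality == "left") nm <- paste0(nm, "_L")
    if (laterality == "right") nm <- paste0(nm, "_R")
    nm
  }
  out <- switch(category,
    NO_MATCH = list(prediction = no_match(), category = "NO_MATCH"),
    WRONG_OAR = {
      other <- entries[entries$concept_id != e$concept_id, ]
      list(
        prediction = other$standard_name[sample.int(nrow(other), 1)],
        category = "WRONG_OAR"
      )
    },
    LATERALITY_OR_LOCALITY = {
      sib <- entries[
        entries$concept_id == e$concept_id &
          entries$standard_name != e$standard_name &
          entries$plurality == e$plurality &
          (entries$laterality != e$laterality |
            !mapply(identical, entries$spatial_qualifier, e$spatial_qualifier)),
      ]
      if (nrow(sib) > 0) {
        list(
          prediction = sib$standard_name[sample.int(nrow(sib), 1)],
          category = "LATERALITY_OR_LOCALITY"
        )
      } else {
        NULL
      }
    },
    PLURALITY = {
      if (e$plurality == "plural") {
        sib <- entries[
          entries$concept_id == e$concept_id & entries$plurality == "singular",
        ]
        syn <- lexicon$synonyms
        cand <- syn[syn$standard_name %in% sib$standard_name & syn$lang == "en", ]
        if (nrow(cand) > 0) {
          term <- cand$term[which.min(nchar(cand$term))]
          list(prediction = title_form(term), category = "PLURALITY")
        } else {
          NULL
        }
      } else {
        NULL
      }
    },
    MISSPELLING = {
      syn <- lexicon$synonyms
      own <- syn[syn$standard_name == e$standard_name & syn$lang == "en", ]
      cand <- if (nrow(own) > 0) {
        title_form(own$term[sample.int(nrow(own), 1)], e$laterality)
      } else {
        tolower(gt)
      }
      if (identical(cand, gt)) cand <- tolower(gt)
      list(prediction = cand, category = "MISSPELLING")
    }
  )
  if (is.null(out)) {
    # category not constructible for this ground truth
    other <- entries[entries$concept_id != e$concept_id, ]
    out <- list(
      prediction = other$standard_name[sample.int(nrow(other), 1)],
      category = "WRONG_OAR"
    )
  }
  out
}

#' Simulated renaming backend with programmed error and variability rates
#'
#' Builds an `rtnomen_backend` over a fixed item table. At temperature 0
#' each item deterministically returns its modal answer: the ground truth
#' with probability `1 - error_rate`, otherwise a wrong answer constructed
#' to belong to the drawn error category (using the lexicon structure; the
#' achieved category is recorded in the backend's `items` table). In
#' sampling mode each inference independently deviates from the modal
#' answer with the configured variability rate, drawing from a small pool of
#' alternative labels.
#'
#' @param items a data frame with `raw_name` and `ground_truth` columns
#'   (e.g. a [generate_corpus()] output or its [deduplicate()] view).
#' @param lexicon a [load_lexicon()] object.
#' @param config a [simulated_backend_config()].
#' @return an `rtnomen_backend`; its `items` element records, per item, the
#'   modal answer, correctness, achieved error category and programmed
#'   confidence.
#' @export
backend_simulated <- function(items, lexicon, config = simulated_backend_config()) {
  stopifnot(
    is.data.frame(items),
    all(c("raw_name", "ground_truth") %in% names(items)),
    inherits(lexicon, "tg263_lexicon")
  )
  items <- as_tibble(items) %>%
    distinct(.data$raw_name, .keep_all = TRUE) %>%
    select("raw_name", "ground_truth")
  tab <- withr::with_seed(config$seed, {
    wrong <- runif(nrow(items)) < config$error_rate
    cats <- rep("NONE", nrow(items))
    modal <- canonical_label(items$ground_truth)
    alts <- vector("list", nrow(items))
    conf <- character(nrow(items))
    for (i in seq_len(nrow(items))) {
      gt <- canonical_label(items$ground_truth[i])
      if (wrong[i]) {
        req <- sample(names(config$category_mix), 1, prob = config$category_mix)
        w <- make_wrong_prediction(gt, req, lexicon)
        modal[i] <- w$prediction
        cats[i] <- w$category
        alt2 <- make_wrong_prediction(gt, "WRONG_OAR", lexicon)$prediction
        alts[[i]] <- setdiff(unique(c(gt, alt2)), modal[i])
        conf[i] <- if (runif(1) < config$p_low_given_wrong) "low" else "high"
      } else {
        alts[[i]] <- make_wrong_prediction(gt, "WRONG_OAR", lexicon)$prediction
        conf[i] <- if (runif(1) < config$p_low_given_correct) "low" else "high"
      }
    }
    items %>% mutate(
      wrong = wrong, modal = modal, category = cats,
      confidence = conf, alts = alts
    )
  })
  structure(
    list(id = "simulated", items = tab, config = config),
    class = c("rtnomen_backend_simulated", "rtnomen_backend")
  )
}

#' @export
predict_backend.rtnomen_backend_simulated <- function(backend, name, config) {
  tab <- backend$items
  i <- match(trimws(name), trimws(tab$raw_name))
  if (is.na(i)) {
    abort(paste0("Simulated backend has no item named '", name, "'"),
      class = "rtnomen_unknown_item"
    )
  }
  label <- tab$modal[i]
  if (config$temperature > 0) {
    v <- if (tab$wrong[i]) backend$config$variability else backend$config$variability_correct
    pool <- tab$alts[[i]]
    if (length(pool) > 0 && runif(1) < v) {
      label <- pool[sample.int(length(pool), 1)]
    }
  }
  conf <- tab$confidence[i]
  new_prediction(
    raw_name = name, predicted_name = label, confidence = conf,
    raw_response = render_response(label, conf), backend_id = backend$id
  )
}
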