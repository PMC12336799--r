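# Name normalization, marker detection and concept resolution.
#
# Clinical structure names encode three things besides the organ concept:
# laterality (left/right/bilateral), a spatial qualifier (cervical, proximal,
# superior, ...) and plurality. Resolution strips those markers, matches the
# residue against the lexicon's multilingual synonym table, and recombines.

#' Normalize a structure name for matching
#'
#' Lowercases, converts underscores and punctuation to spaces, drops digits
#' and collapses whitespace. This is the canonical form in which synonym
#' terms are compared; it is deliberately lossy (case and separators carry no
#' anatomical meaning) while keeping diacritics intact.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_name("Glnd_Lacrimal_L")
#' @export
normalize_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[_\\.,;:/\\\\()\\[\\]{}+*'\"!?&<>=#%-]", " ", x, perl = TRUE)
  x <- gsub("[0-9]+", " ", x)
  stringr::str_squish(x)
}

# marker vocabularies ---------------------------------------------------------

laterality_markers <- function() {
  list(
    left = c("l", "li", "lt", "left", "links", "linker", "linkse", "sin"),
    right = c("r", "re", "rt", "right", "rechts", "rechter", "rechtse", "dex", "dx"),
    bilateral = c(
      "bds", "bdz", "bd", "bilat", "bilateral", "bilateraal", "both",
      "beide", "beiderseits", "beidseits", "tot", "total", "totaal", "gesamt"
    )
  )
}

#' Spatial qualifier aliases
#'
#' Maps normalized tokens to canonical TG-263 qualifier tokens. Users can pass
#' an extended table to [parse_name()] when their lexicon uses additional
#' qualifiers.
#'
#' @return named character vector (names = aliases, values = canonical token).
#' @export
qualifier_aliases <- function() {
  c(
    cerv = "Cerv", cervical = "Cerv", zervikal = "Cerv", zervikales = "Cerv",
    cervicaal = "Cerv",
    thor = "Thor", thoracic = "Thor", thorakal = "Thor", thorakales = "Thor",
    thoracaal = "Thor",
    prox = "Prox", proximal = "Prox", proximale = "Prox", proximaler = "Prox",
    proximaal = "Prox",
    dist = "Dist", distal = "Dist", distaal = "Dist",
    sup = "Sup", superior = "Sup", cran = "Sup", cranial = "Sup",
    inf = "Inf", inferior = "Inf", caud = "Inf", caudal = "Inf",
    ant = "Ant", anterior = "Ant",
    post = "Post", posterior = "Post"
  )
}

# split a raw name into original-case tokens plus their normalized forms
tokenize_name <- function(name) {
  tokens <- strsplit(gsub("[_\\s]+", " ", name, perl = TRUE), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  tibble(token = tokens, norm = normalize_name(tokens))
}

# Core resolver: one name -> concept, entry, components.
# Stages: (1) exact standard name; (2) whole-string synonym match;
# (3) marker stripping, then synonym match on the residue.
resolve_one <- function(name, lexicon, aliases = qualifier_aliases()) {
  out <- list(
    input = name, resolved = FALSE, concept_id = NA_character_,
    standard_name = NA_character_, laterality = "none",
    spatial_qualifier = NA_character_, plurality = "singular",
    concept_tokens = list(character()), exact = FALSE
  )
  nm <- trimws(name)
  if (!nzchar(nm)) {
    abort("parse_name() requires a non-empty name", class = "rtnomen_invalid_input")
  }
  entries <- lexicon$entries

  hit <- match(nm, entries$standard_name)
  toks <- tokenize_name(nm)
  lat_tab <- laterality_markers()
  is_left <- toks$norm %in% lat_tab$left
  is_right <- toks$norm %in% lat_tab$right
  is_bilat <- toks$norm %in% lat_tab$bilateral
  is_qual <- toks$norm %in% names(aliases)
  residual <- toks$token[!(is_left | is_right | is_bilat | is_qual)]

  if (!is.na(hit)) {
    e <- entries[hit, ]
    out$resolved <- TRUE
    out$exact <- TRUE
    out$concept_id <- e$concept_id
    out$standard_name <- e$standard_name
    out$laterality <- e$laterality
    out$spatial_qualifier <- e$spatial_qualifier
    out$plurality <- e$plurality
    out$concept_tokens <- list(residual)
    return(out)
  }

  lat <- if (any(is_left) && !any(is_right)) {
    "left"
  } else if (any(is_right) && !any(is_left)) {
    "right"
  } else {
    "none"
  }
  bilat <- any(is_bilat)
  qual <- if (any(is_qual)) unname(aliases[toks$norm[is_qual][1]]) else NA_character_

  norm_full <- normalize_name(nm)
  norm_resid <- normalize_name(paste(residual, collapse = " "))

  syn <- lexicon$synonyms
  std_norm <- normalize_name(entries$standard_name)

  match_rows <- function(phrase) {
    if (!nzchar(phrase)) {
      return(tibble(standard_name = character(), concept_id = character()))
    }
    hits <- syn[syn$term_norm == phrase, c("standard_name", "concept_id")]
    std_hit <- which(std_norm == phrase)
    if (length(std_hit) > 0) {
      hits <- bind_rows(hits, entries[std_hit, c("standard_name", "concept_id")])
    }
    distinct(hits)
  }

  used_markers <- FALSE
  rows <- match_rows(norm_full)
  if (nrow(rows) == 0 && norm_resid != norm_full) {
    rows <- match_rows(norm_resid)
    used_markers <- TRUE
  }
  if (nrow(rows) == 0) {
    # unresolvable: report marker-derived components only
    out$laterality <- lat
    out$spatial_qualifier <- qual
    out$plurality <- if (bilat) "plural" else "singular"
    out$concept_tokens <- list(residual)
    return(out)
  }

  concept <- names(sort(table(rows$concept_id), decreasing = TRUE))[1]
  rows <- rows[rows$concept_id == concept, ]
  owners <- entries[match(rows$standard_name, entries$standard_name), ]

  if (!used_markers) {
    # whole-string synonym match: components come from the owning entries
    lat <- if (length(unique(owners$laterality)) == 1) owners$laterality[1] else "none"
    qual <- if (length(unique(owners$spatial_qualifier)) == 1) {
      owners$spatial_qualifier[1]
    } else {
      NA_character_
    }
    plur <- if (all(owners$plurality == "plural")) "plural" else "singular"
  } else {
    plur <- if (bilat || all(owners$plurality == "plural")) "plural" else "singular"
  }
  if (used_markers && bilat) plur <- "plural"

  out$resolved <- TRUE
  out$concept_id <- concept
  out$laterality <- lat
  out$spatial_qualifier <- qual
  out$plurality <- if (exists("plur", inherits = FALSE)) plur else "singular"
  out$concept_tokens <- list(residual)
  out$standard_name <- select_entry(
    entries[entries$concept_id == concept, ],
    lat, qual, out$plurality
  )
  out
}

# deterministic entry selection within a concept: strong preference for the
# requested laterality, then qualifier, then plurality; ties break in lexicon
# order
select_entry <- function(cand, lat, qual, plur) {
  if (nrow(cand) == 0) {
    return(NA_character_)
  }
  qual_score <- ifelse(
    (is.na(qual) & is.na(cand$spatial_qualifier)) |
      (!is.na(qual) & !is.na(cand$spatial_qualifier) & cand$spatial_qualifier == qual),
    2L, 0L
  )
  lat_score <- ifelse(cand$laterality == lat, 4L, 0L)
  if (plur == "plural") {
    lat_score <- pmax(lat_score, ifelse(cand$laterality == "bilateral", 4L, 0L))
  }
  plur_score <- ifelse(cand$plurality == plur, 1L, 0L)
  score <- lat_score + qual_score + plur_score
  cand$standard_name[which.max(score)]
}

#' Decompose a structure name into components
#'
#' Splits a (raw or standardized) structure name into organ-concept tokens, a
#' laterality, an optional spatial qualifier and a plurality. Laterality is
#' detected from marker tokens (`_L`, `li`, `links`, `rechts`, `bds`, ...),
#' qualifiers from a configurable alias table, and plurality from bilateral
#' markers or from the matched lexicon synonym. The function is deterministic
#' and total on non-empty strings; names that cannot be resolved against the
#' lexicon still yield marker-derived components.
#'
#' @param name character vector of structure names (non-empty).
#' @param lexicon a [load_lexicon()] object.
#' @param aliases qualifier alias table, see [qualifier_aliases()].
#' @return a tibble with one row per name: `name`, `concept_tokens`
#'   (list-column), `laterality`, `spatial_qualifier`, `plurality`,
#'   `concept_id`, `resolved`.
#' @examples
#' lex <- load_lexicon()
#' parse_name(c("Glnd_Lacrimal_L", "SpinalCord_Cerv", "Niere bds"), lex)
#' @export
parse_name <- function(name, lexicon, aliases = qualifier_aliases()) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  if (length(name) == 0) {
    abort("parse_name() requires at least one name", class = "rtnomen_invalid_input")
  }
  res <- purrr::map(as.character(name), resolve_one, lexicon = lexicon, aliases = aliases)
  tibble(
    name = as.character(name),
    concept_tokens = purrr::map(res, ~ .x$concept_tokens[[1]]),
    laterality = purrr::map_chr(res, "laterality"),
    spatial_qualifier = purrr::map_chr(res, "spatial_qualifier"),
    plurality = purrr::map_chr(res, "plurality"),
    concept_id = purrr::map_chr(res, "concept_id"),
    resolved = purrr::map_lgl(res, "resolved")
  )
}

#' Recompose a structure name from parsed components
#'
#' Inverse of [parse_name()] for valid TG-263 names: concept tokens joined by
#' underscores, followed by the spatial qualifier token and a `_L`/`_R`
#' laterality suffix.
#'
#' @param components one row of the tibble returned by [parse_name()].
#' @return a character string.
#' @export
compose_name <- function(components) {
  stopifnot(is.data.frame(components), nrow(components) == 1)
  parts <- components$concept_tokens[[1]]
  if (!is.na(components$spatial_qualifier)) {
    parts <- c(parts, components$spatial_qualifier)
  }
  if (components$laterality == "left") parts <- c(parts, "L")
  if (components$laterality == "right") parts <- c(parts, "R")
  paste(parts, collapse = "_")
}

#' Do two names denote the same organ concept?
#'
#' Both names are resolved through the lexicon (standard names and synonyms,
#' after marker stripping); the result is `TRUE` when both map to the same
#' `concept_id`, `FALSE` when both resolve but to different concepts, and
#' `NA` when either name is unresolvable. The relation is symmetric and, on
#' resolvable names, reflexive and transitive.
#'
#' @param a,b character vectors (recycled to a common length).
#' @param lexicon a [load_lexicon()] object.
#' @return logical vector (with `NA` marking unresolvable comparisons).
#' @examples
#' lex <- load_lexicon()
#' same_concept("Lacrimal_Gland_L", "Glnd_Lacrimal_L", lex)
#' same_concept("Pharynx", "Musc_Constrict", lex)
#' @export
same_concept <- function(a, b, lexicon) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ca <- parse_name(a, lexicon)$concept_id
  cb <- parse_name(b, lexicon)$concept_id
  ifelse(is.na(ca) | is.na(cb), NA, ca == cb)
}
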