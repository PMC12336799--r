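#' Load a TG-263 lexicon file
#'
#' Reads a delimited lexicon of TG-263 standard structure names. The file is
#' tab-separated with a header and the columns `standard_name`, `concept_id`,
#' `category` (organ / substructure / composite), `laterality` (left / right /
#' bilateral / none), `spatial_qualifier` (token such as `Cerv`, may be empty),
#' `plurality` (singular / plural) and `synonyms` (pipe-separated `lang:term`
#' pairs, languages `en`, `de`, `nl`). Lines starting with `#` are comments.
#'
#' All entries of one organ concept share a `concept_id`; synonym terms are
#' matched after normalization (lowercase, punctuation collapsed to spaces),
#' and one normalized term may only belong to a single concept.
#'
#' @param path path to a lexicon file. The default is the curated subset
#'   bundled with the package (>= 100 entries).
#' @param version_tag free-text tag stored on the lexicon (defaults to the
#'   file name).
#' @return a `tg263_lexicon` object: a list with `entries` (tibble, one row
#'   per standard name), `synonyms` (tibble of normalized term -> concept
#'   mappings) and `version_tag`.
#' @examples
#' lex <- load_lexicon()
#' lex
#' @export
load_lexicon <- function(path = rtnomen_example("tg263_lexicon.tsv"),
                         version_tag = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("Lexicon file not found: ", path), class = "rtnomen_missing_file")
  }
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c(
    "standard_name", "concept_id", "category", "laterality",
    "spatial_qualifier", "plurality", "synonyms"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Lexicon file lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "rtnomen_lexicon_format"
    )
  }
  entries <- raw %>%
    mutate(
      standard_name = trimws(.data$standard_name),
      concept_id = trimws(.data$concept_id),
      laterality = dplyr::coalesce(trimws(.data$laterality), "none"),
      spatial_qualifier = dplyr::na_if(trimws(dplyr::coalesce(.data$spatial_qualifier, "")), ""),
      plurality = dplyr::coalesce(trimws(.data$plurality), "singular"),
      synonyms = dplyr::coalesce(.data$synonyms, "")
    )
  entries$laterality[entries$laterality == ""] <- "none"
  entries$plurality[entries$plurality == ""] <- "singular"

  validate_enum(entries, "category", c("organ", "substructure", "composite"))
  validate_enum(entries, "laterality", c("left", "right", "bilateral", "none"))
  validate_enum(entries, "plurality", c("singular", "plural"))

  dup <- entries$standard_name[duplicated(entries$standard_name)]
  if (length(dup) > 0) {
    abort(
      paste0("Duplicate standard_name in lexicon: ", paste(unique(dup), collapse = ", ")),
      class = "rtnomen_duplicate_name"
    )
  }

  syn <- parse_synonym_column(entries)
  # every normalized synonym term must resolve to exactly one concept
  clash <- syn %>%
    distinct(.data$term_norm, .data$concept_id) %>%
    dplyr::count(.data$term_norm) %>%
    filter(.data$n > 1)
  if (nrow(clash) > 0) {
    abort(
      paste0(
        "Synonym mapped to more than one concept_id: ",
        paste(clash$term_norm, collapse = ", ")
      ),
      class = "rtnomen_ambiguous_synonym"
    )
  }

  check_laterality_siblings(entries)

  structure(
    list(entries = entries, synonyms = syn, version_tag = version_tag),
    class = "tg263_lexicon"
  )
}

#' Path to a file bundled with rtnomen
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names).
#' @examples
#' rtnomen_example()
#' @export
rtnomen_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "rtnomen")))
  }
  path <- system.file("extdata", file, package = "rtnomen")
  if (identical(path, "")) {
    abort(paste0("No bundled file named '", file, "'"), class = "rtnomen_missing_file")
  }
  path
}

#' @export
print.tg263_lexicon <- function(x, ...) {
  cat(
    "<tg263_lexicon> ", nrow(x$entries), " entries, ",
    length(unique(x$entries$concept_id)), " concepts (",
    x$version_tag, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Test whether a name is a valid TG-263 standard name
#'
#' Validity is exact, case-sensitive membership of the lexicon's standard
#' names after trimming leading/trailing whitespace; synonyms and
#' reorderings of a standard name are not valid.
#'
#' @param name character vector of names to test.
#' @param lexicon a [load_lexicon()] object.
#' @return logical vector.
#' @examples
#' lex <- load_lexicon()
#' is_valid_tg263(c("Kidneys", "kidneys", "Lacrimal_Gland_L"), lex)
#' @export
is_valid_tg263 <- function(name, lexicon) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  trimws(as.character(name)) %in% lexicon$entries$standard_name
}

# ---- internal helpers -------------------------------------------------------

validate_enum <- function(entries, col, allowed) {
  bad <- !entries[[col]] %in% allowed
  if (any(bad)) {
    abort(
      paste0(
        "Invalid ", col, " value(s) ",
        paste(unique(entries[[col]][bad]), collapse = ", "),
        " for entry: ", paste(entries$standard_name[bad], collapse = ", ")
      ),
      class = "rtnomen_lexicon_format"
    )
  }
  invisible(TRUE)
}

# long table of normalized synonym terms; the standard name itself is also
# registered as a resolvable term of its own entry
parse_synonym_column <- function(entries) {
  per_entry <- purrr::map2(entries$standard_name, entries$synonyms, function(nm, syn) {
    pairs <- if (nzchar(syn)) strsplit(syn, "|", fixed = TRUE)[[1]] else character()
    bad <- !grepl("^[a-z]{2}:", pairs)
    if (any(bad)) {
      abort(
        paste0(
          "Malformed synonym (expected 'lang:term') for entry ", nm, ": ",
          paste(pairs[bad], collapse = ", ")
        ),
        class = "rtnomen_lexicon_format"
      )
    }
    tibble(
      standard_name = nm,
      lang = substr(pairs, 1, 2),
      term = substring(pairs, 4)
    )
  })
  per_entry <- bind_rows(per_entry)
  if (nrow(per_entry) == 0) {
    return(tibble(
      standard_name = character(), lang = character(), term = character(),
      term_norm = character(), concept_id = character()
    ))
  }
  syn <- per_entry %>%
    mutate(term_norm = normalize_name(.data$term)) %>%
    filter(nzchar(.data$term_norm)) %>%
    distinct(.data$standard_name, .data$lang, .data$term, .data$term_norm)
  syn %>%
    left_join(
      entries %>% select("standard_name", "concept_id"),
      by = "standard_name"
    )
}

check_laterality_siblings <- function(entries) {
  sided <- entries %>% filter(.data$laterality %in% c("left", "right"))
  if (nrow(sided) == 0) {
    return(invisible(TRUE))
  }
  key <- sub("_[LR]$", "", sided$standard_name)
  grp <- split(sided, list(sided$concept_id, key, sided$plurality), drop = TRUE)
  for (g in grp) {
    if (length(unique(g$laterality)) != nrow(g)) next
    stems <- unique(sub("_[LR]$", "", g$standard_name))
    if (length(stems) > 1) {
      abort(
        paste0(
          "Left/right entries of concept ", g$concept_id[1],
          " differ beyond the laterality token: ",
          paste(g$standard_name, collapse = ", ")
        ),
        class = "rtnomen_lexicon_format"
      )
    }
  }
  invisible(TRUE)
}
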