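#' Read a tabular list of raw structure names
#'
#' Reads the package's delimited-text dialect for structure records: a TSV
#' with a `raw_name` column and optional `center_id`, `patient_id`,
#' `language_hint` (`en`/`de`/`nl`/`unknown`) and `ground_truth` columns.
#'
#' @param path path to a TSV file.
#' @return a tibble of raw-structure records; missing optional columns are
#'   added as `NA`.
#' @export
read_structure_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "rtnomen_missing_file")
  }
  df <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"raw_name" %in% names(df)) {
    abort(
      paste0("Structure table lacks a raw_name column: ", path),
      class = "rtnomen_table_format"
    )
  }
  for (col in c("center_id", "patient_id", "language_hint", "ground_truth")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  bad <- is.na(df$raw_name) | !nzchar(trimws(df$raw_name))
  if (any(bad)) {
    abort(
      paste0("Empty raw_name in row(s): ", paste(which(bad), collapse = ", ")),
      class = "rtnomen_table_format"
    )
  }
  as_tibble(df)
}

#' Default exclusion rules
#'
#' Pattern rules (Perl regular expressions, matched case-insensitively)
#' reproducing the usual manual curation of radiotherapy structure sets:
#' target volumes (PTV/CTV/GTV/ITV, boost) and auxiliary planning structures
#' (couch, table, bolus, masks, isocenter markers, help/optimization
#' structures) are excluded before renaming. The set is fully user-overridable;
#' each rule is named by its tag.
#'
#' @return named character vector of regular expressions.
#' @examples
#' default_exclusion_rules()
#' @export
default_exclusion_rules <- function() {
  c(
    target = "(ptv|ctv|gtv|itv|boost)",
    aux = paste0(
      "(couch|table|bolus|mask(e|er)?|",
      "(^|[^a-z])iso([^a-z]|$)|",
      "(^|[^a-z])(help|hulp|hilfs?)|",
      "(^|[^a-z])opt([^a-z]|$)|",
      "referen[zc]|marker|dummy)"
    )
  )
}

#' Partition structure records into kept and excluded
#'
#' Applies exclusion rules to raw structure names: a record is excluded when
#' any rule matches, and carries the tag of the *first* matching rule for
#' auditability. The partition is exhaustive and disjoint
#' (`nrow(kept) + nrow(excluded) == nrow(records)`).
#'
#' @param records a data frame with a `raw_name` column.
#' @param rules named character vector of regular expressions; names become
#'   exclusion tags. An empty set keeps everything.
#' @return a list with tibbles `kept` and `excluded` (the latter with an
#'   extra `rule_tag` column).
#' @examples
#' recs <- tibble::tibble(raw_name = c("Niere bds", "PTV56", "Couch"))
#' filter_structures(recs)
#' @export
filter_structures <- function(records, rules = default_exclusion_rules()) {
  stopifnot(is.data.frame(records), "raw_name" %in% names(records))
  records <- as_tibble(records)
  if (length(rules) == 0) {
    return(list(
      kept = records,
      excluded = records[0, , drop = FALSE] %>% mutate(rule_tag = character())
    ))
  }
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    abort("Every exclusion rule must be named (the name is its tag)",
      class = "rtnomen_rule_error"
    )
  }
  hits <- matrix(FALSE, nrow = nrow(records), ncol = length(rules))
  for (j in seq_along(rules)) {
    ok <- tryCatch(
      suppressWarnings(grepl(rules[[j]], records$raw_name, perl = TRUE, ignore.case = TRUE)),
      error = function(e) {
        abort(
          paste0(
            "Malformed exclusion pattern for rule '", names(rules)[j], "': ",
            conditionMessage(e)
          ),
          class = "rtnomen_rule_error"
        )
      }
    )
    hits[, j] <- ok
  }
  excluded_idx <- rowSums(hits) > 0
  first_rule <- apply(hits, 1, function(r) if (any(r)) names(rules)[which(r)[1]] else NA_character_)
  list(
    kept = records[!excluded_idx, , drop = FALSE],
    excluded = records[excluded_idx, , drop = FALSE] %>%
      mutate(rule_tag = first_rule[excluded_idx])
  )
}

#' Collapse structure records into unique names
#'
#' Groups records by the trimmed raw name (case-sensitive by default),
#' pooled across centers, mirroring the refinement of a full clinical corpus
#' into its unique-name view. Multiplicities are conserved:
#' `sum(multiplicity)` equals the number of input records.
#'
#' @param records a data frame with a `raw_name` column; `center_id`,
#'   `language_hint` and `ground_truth` columns are carried along
#'   (provenance as a collapsed center set; first non-missing value for the
#'   other two).
#' @param case_sensitive if `FALSE`, names differing only by case collapse
#'   together (the reported `raw_name` is the first seen spelling).
#' @return a tibble with `raw_name`, `multiplicity`, `source_centers`, and —
#'   when present in the input — `language_hint` and `ground_truth`; sorted
#'   by descending multiplicity, then name.
#' @examples
#' deduplicate(tibble::tibble(raw_name = c("Herz", "Herz", "Heart")))
#' @export
deduplicate <- function(records, case_sensitive = TRUE) {
  stopifnot(is.data.frame(records), "raw_name" %in% names(records))
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(
      raw_name = character(), multiplicity = integer(),
      source_centers = character()
    ))
  }
  records <- records %>%
    mutate(
      .trim = trimws(.data$raw_name),
      .key = if (case_sensitive) trimws(.data$raw_name) else tolower(trimws(.data$raw_name))
    )
  if (!"center_id" %in% names(records)) records$center_id <- NA_character_
  first_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 0) x[1] else NA_character_
  }
  out <- records %>%
    group_by(.data$.key) %>%
    summarise(
      raw_name = .data$.trim[1],
      multiplicity = dplyr::n(),
      source_centers = paste(sort(unique(stats::na.omit(.data$center_id))), collapse = ","),
      language_hint = if ("language_hint" %in% names(records)) {
        first_or_na(.data$language_hint)
      } else {
        NA_character_
      },
      ground_truth = if ("ground_truth" %in% names(records)) {
        first_or_na(.data$ground_truth)
      } else {
        NA_character_
      },
      .groups = "drop"
    ) %>%
    select(-".key") %>%
    arrange(desc(.data$multiplicity), .data$raw_name)
  if (!"language_hint" %in% names(records)) out$language_hint <- NULL
  if (!"ground_truth" %in% names(records)) out$ground_truth <- NULL
  out
}
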