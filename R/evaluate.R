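error_categories <- function() {
  c("NONE", "WRONG_OAR", "LATERALITY_OR_LOCALITY", "PLURALITY", "MISSPELLING", "NO_MATCH")
}

#' Classify a misassignment into the five-category error taxonomy
#'
#' Deterministic decision cascade over a `(prediction, ground truth)` pair;
#' the first matching rule wins:
#'
#' 1. exact equality (trimmed, case-sensitive; no-match only equals
#'    no-match) -> `NONE`;
#' 2. prediction is the no-match sentinel -> `NO_MATCH`;
#' 3. same organ concept but laterality or spatial qualifier differs ->
#'    `LATERALITY_OR_LOCALITY` (left/right and regional designations such as
#'    cervical or superior share one category);
#' 4. same concept but singular/plural form differs -> `PLURALITY`;
#' 5. same concept (via synonym resolution) but not the exact TG-263
#'    spelling -> `MISSPELLING`;
#' 6. otherwise -> `WRONG_OAR`.
#'
#' @param prediction character vector of predicted names (or [no_match()]).
#' @param ground_truth character vector of TG-263 ground-truth labels (or
#'   [no_match()]); must be covered by the lexicon.
#' @param lexicon a [load_lexicon()] object.
#' @return character vector of category labels (see `error_categories`),
#'   `NONE` marking correct predictions.
#' @examples
#' lex <- load_lexicon()
#' classify_error("SpinalCord", "SpinalCord_Cerv", lex)
#' classify_error("Kidney", "Kidneys", lex)
#' @export
classify_error <- function(prediction, ground_truth, lexicon) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  n <- max(length(prediction), length(ground_truth))
  pred <- canonical_label(rep_len(as.character(prediction), n))
  gt <- canonical_label(rep_len(as.character(ground_truth), n))

  gt_ok <- is_no_match(gt) | is_valid_tg263(gt, lexicon)
  if (any(!gt_ok)) {
    abort(
      paste0(
        "Ground truth not covered by the lexicon: ",
        paste(unique(gt[!gt_ok]), collapse = ", ")
      ),
      class = "rtnomen_gt_not_in_lexicon"
    )
  }

  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- classify_one(pred[i], gt[i], lexicon)
  }
  out
}

classify_one <- function(pred, gt, lexicon) {
  if (is.na(pred)) {
    return("WRONG_OAR")
  }
  if (identical(pred, gt)) {
    return("NONE")
  }
  if (is_no_match(pred)) {
    return("NO_MATCH")
  }
  if (is_no_match(gt)) {
    # a concrete prediction where no TG-263 name exists
    return("WRONG_OAR")
  }
  pc <- parse_name(pred, lexicon)
  gc <- parse_name(gt, lexicon)
  same <- !is.na(pc$concept_id) && !is.na(gc$concept_id) &&
    pc$concept_id == gc$concept_id
  if (!same) {
    return("WRONG_OAR")
  }
  lat_differs <- pc$laterality != gc$laterality
  qual_differs <- !identical(pc$spatial_qualifier, gc$spatial_qualifier)
  if (lat_differs || qual_differs) {
    return("LATERALITY_OR_LOCALITY")
  }
  if (pc$plurality != gc$plurality) {
    return("PLURALITY")
  }
  "MISSPELLING"
}

#' Score predictions against ground truth
#'
#' Joins predictions with ground-truth labels and adds the correctness flag
#' (`correct`: exact trimmed, case-sensitive string equality, with no-match
#' equal only to no-match) and the five-category `error_type`
#' (see [classify_error()]; `NONE` for correct records). Records without a
#' ground-truth label are dropped and reported via a message and the
#' `"excluded"` attribute.
#'
#' @param records a data frame with columns `predicted_name` and
#'   `ground_truth` (e.g. a [rename_batch()] result joined to a corpus);
#'   other columns (`raw_name`, `confidence`, `multiplicity`, `center_id`,
#'   ...) are carried through.
#' @param lexicon a [load_lexicon()] object.
#' @return the scored tibble, one row per input record.
#' @export
score_predictions <- function(records, lexicon) {
  stopifnot(
    is.data.frame(records),
    all(c("predicted_name", "ground_truth") %in% names(records))
  )
  records <- as_tibble(records)
  no_gt <- is.na(records$ground_truth) | !nzchar(trimws(records$ground_truth))
  if (any(no_gt)) {
    message(sum(no_gt), " record(s) without ground truth excluded from scoring")
  }
  dropped <- records[no_gt, , drop = FALSE]
  records <- records[!no_gt, , drop = FALSE]
  records <- records %>%
    mutate(
      predicted_name = canonical_label(.data$predicted_name),
      ground_truth = canonical_label(.data$ground_truth),
      error_type = classify_error(.data$predicted_name, .data$ground_truth, lexicon),
      correct = .data$error_type == "NONE"
    )
  attr(records, "excluded") <- dropped
  records
}

#' Summarise renaming accuracy
#'
#' Computes the two headline metrics of a renaming experiment: *unique
#' accuracy*, the fraction of distinct raw names renamed correctly, and
#' *overall accuracy*, the multiplicity-weighted fraction (every clinical
#' occurrence of a name counts). When all multiplicities are 1 the two
#' coincide. Optional per-center and per-anatomical-region breakdowns are
#' computed from `center_id` / `region` columns, and the error histogram is
#' tallied over misassignments only.
#'
#' @param scored a tibble from [score_predictions()], one row per unique raw
#'   name; an optional `multiplicity` column weights the overall metric
#'   (default 1).
#' @return an `accuracy_report` object; see [tidy.accuracy_report()] and
#'   [glance.accuracy_report()].
#' @export
accuracy_report <- function(scored) {
  stopifnot(is.data.frame(scored), all(c("correct", "error_type") %in% names(scored)))
  if (nrow(scored) == 0) {
    abort("Cannot summarise an empty record set", class = "rtnomen_empty_input")
  }
  if (!"multiplicity" %in% names(scored)) scored$multiplicity <- 1L
  acc <- function(df) {
    tibble(
      n_unique = nrow(df),
      n_total = sum(df$multiplicity),
      unique_accuracy = mean(df$correct),
      overall_accuracy = sum(df$correct * df$multiplicity) / sum(df$multiplicity)
    )
  }
  per_center <- if ("center_id" %in% names(scored) && any(!is.na(scored$center_id))) {
    scored %>%
      group_by(center_id = .data$center_id) %>%
      dplyr::group_modify(~ acc(.x)) %>%
      ungroup()
  } else {
    NULL
  }
  per_region <- if ("region" %in% names(scored) && any(!is.na(scored$region))) {
    scored %>%
      group_by(region = .data$region) %>%
      dplyr::group_modify(~ acc(.x)) %>%
      ungroup()
  } else {
    NULL
  }
  hist <- scored %>%
    filter(!.data$correct) %>%
    dplyr::count(error_type = factor(.data$error_type,
      levels = setdiff(error_categories(), "NONE")
    ), .drop = FALSE) %>%
    rename(count = "n")
  structure(
    list(
      overall = acc(scored),
      per_center = per_center,
      per_region = per_region,
      error_histogram = hist
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  o <- x$overall
  cat("<accuracy_report>\n")
  cat(sprintf(
    "  unique accuracy:  %.4f  (%d distinct names)\n",
    o$unique_accuracy, o$n_unique
  ))
  cat(sprintf(
    "  overall accuracy: %.4f  (%d name instances)\n",
    o$overall_accuracy, o$n_total
  ))
  errs <- x$error_histogram %>% filter(.data$count > 0)
  if (nrow(errs) > 0) {
    cat("  errors:", paste0(errs$error_type, "=", errs$count, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an accuracy report
#'
#' @param x an [accuracy_report()] object.
#' @param ... unused.
#' @return a tibble with one row per reporting group (`combined` plus any
#'   per-center / per-region groups) and the accuracy columns.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  rows <- list(x$overall %>% mutate(group = "combined", level = "combined"))
  if (!is.null(x$per_center)) {
    rows <- c(rows, list(
      x$per_center %>% rename(level = "center_id") %>% mutate(group = "center")
    ))
  }
  if (!is.null(x$per_region)) {
    rows <- c(rows, list(
      x$per_region %>% rename(level = "region") %>% mutate(group = "region")
    ))
  }
  bind_rows(rows) %>%
    select("group", "level", "n_unique", "n_total", "unique_accuracy", "overall_accuracy")
}

#' Glance at an accuracy report
#'
#' @param x an [accuracy_report()] object.
#' @param ... unused.
#' @return a one-row tibble with the combined metrics and total error count.
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  x$overall %>% mutate(n_errors = sum(x$error_histogram$count))
}

#' Plot an accuracy report
#'
#' Bar panel of the error-type histogram alongside the two accuracy metrics.
#'
#' @param object an [accuracy_report()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  hist <- object$error_histogram
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$error_type, y = .data$count)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(
      x = NULL, y = "misassignments",
      title = "Renaming error types",
      subtitle = sprintf(
        "unique accuracy %.3f, overall accuracy %.3f",
        object$overall$unique_accuracy, object$overall$overall_accuracy
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
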