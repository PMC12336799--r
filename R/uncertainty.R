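# Monte-Carlo label-entropy uncertainty and confidence/error association.
#
# Repeated stochastic inferences of the same input give a label distribution;
# its Shannon entropy H = -sum p_i ln p_i (in nats) measures output
# variability. H > 0 iff at least two distinct labels occurred, which is the
# uncertainty flag used as a binary error detector.

#' Shannon entropy of a label multiset
#'
#' Computes \eqn{H = -\sum_i p_i \ln p_i} where \eqn{p_i} is the relative
#' frequency of the i-th distinct label, in nats (natural logarithm; the
#' base does not affect the H > 0 flag). Labels are compared after
#' whitespace trimming, case-sensitively. Invariant under permutation and
#' relabeling; `0 <= H <= log(n)` with equality at a single label and at the
#' uniform distribution respectively.
#'
#' @param labels non-empty character vector of sampled labels ([no_match()]
#'   is a legal label).
#' @return entropy in nats (length-1 numeric).
#' @examples
#' shannon_entropy(rep("SpinalCord", 10)) # 0
#' shannon_entropy(c(rep("A", 5), rep("B", 5))) # log(2)
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0 || all(is.na(labels))) {
    abort("shannon_entropy() requires a non-empty label list",
      class = "rtnomen_invalid_input"
    )
  }
  p <- table(trimws(labels[!is.na(labels)]))
  p <- as.numeric(p) / sum(p)
  -sum(p * log(p))
}

#' Phi (binary Pearson) correlation of two 0/1 vectors
#'
#' Equals the Pearson product-moment correlation applied to binary vectors;
#' on the 2x2 contingency table with cells a, b, c, d it is
#' \eqn{(ad - bc) / \sqrt{(a+b)(c+d)(a+c)(b+d)}}. When any margin is zero the
#' coefficient is undefined: the result carries `phi = NA` and
#' `degenerate = TRUE` so "undefined" cannot be mistaken for "no
#' association".
#'
#' @param x,y equal-length vectors coercible to 0/1 (logical or numeric).
#' @return a `binary_assoc` object: list with `phi`, `counts` (2x2 matrix),
#'   `degenerate`, `n`.
#' @examples
#' phi_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
phi_correlation <- function(x, y) {
  x <- as.integer(as.logical(x))
  y <- as.integer(as.logical(y))
  if (length(x) != length(y)) {
    abort("phi_correlation() requires equal-length vectors",
      class = "rtnomen_invalid_input"
    )
  }
  if (length(x) < 2) {
    abort("phi_correlation() requires at least two observations",
      class = "rtnomen_invalid_input"
    )
  }
  if (anyNA(x) || anyNA(y)) {
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]
    y <- y[keep]
  }
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  counts <- matrix(c(a, c_, b, d),
    nrow = 2,
    dimnames = list(x = c("1", "0"), y = c("1", "0"))
  )
  margins <- c(a + b, c_ + d, a + c_, b + d)
  degenerate <- any(margins == 0)
  phi <- if (degenerate) {
    NA_real_
  } else {
    (a * d - b * c_) / sqrt(prod(as.numeric(margins)))
  }
  structure(
    list(phi = phi, counts = counts, degenerate = degenerate, n = a + b + c_ + d),
    class = "binary_assoc"
  )
}

#' @export
print.binary_assoc <- function(x, ...) {
  if (x$degenerate) {
    cat("<binary_assoc> phi undefined (degenerate margin), n =", x$n, "\n")
  } else {
    cat(sprintf("<binary_assoc> phi = %.4f, n = %d\n", x$phi, x$n))
  }
  invisible(x)
}

#' Tidy a binary association
#'
#' @param x a [phi_correlation()] result.
#' @param ... unused.
#' @return a one-row tibble with `phi`, `degenerate`, `n` and the four cell
#'   counts.
#' @method tidy binary_assoc
#' @export
tidy.binary_assoc <- function(x, ...) {
  tibble(
    phi = x$phi, degenerate = x$degenerate, n = x$n,
    a = x$counts[1, 1], b = x$counts[1, 2],
    c = x$counts[2, 1], d = x$counts[2, 2]
  )
}

#' Repeated stochastic inferences for one structure name
#'
#' Collects `k` labels for `name` from a backend in sampling mode
#' (temperature > 0, nucleus sampling). Labels are whitespace-trimmed before
#' downstream counting; [no_match()] is a legal label. With a seeded config
#' the sample list is reproducible; with temperature 0 a warning is emitted
#' because all samples are identical by the deterministic contract.
#'
#' @param name a single raw structure name.
#' @param backend an `rtnomen_backend`.
#' @param k number of repeated inferences (default 10).
#' @param config a [backend_config()]; defaults to temperature 1,
#'   top-p 0.95.
#' @return a tibble with columns `sample_index`, `label`, `ok`; the
#'   `incomplete` attribute flags missing samples (backend failures).
#' @export
sample_predictions <- function(name, backend, k = 10,
                               config = backend_config(temperature = 1, top_p = 0.95)) {
  stopifnot(length(name) == 1, k >= 1)
  if (config$temperature == 0) {
    warn("temperature is 0: all samples will be identical by the deterministic contract")
  }
  run <- function() {
    purrr::map(seq_len(k), function(i) {
      tryCatch(
        {
          p <- predict_backend(backend, name, config)
          tibble(sample_index = i, label = trimws(p$predicted_name), ok = TRUE)
        },
        error = function(e) tibble(sample_index = i, label = NA_character_, ok = FALSE)
      )
    })
  }
  out <- if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
  out <- bind_rows(out)
  attr(out, "incomplete") <- any(!out$ok)
  out
}

#' Per-structure uncertainty profile
#'
#' Runs [sample_predictions()] for every name and summarises each label
#' distribution: number of distinct labels `n_distinct`, Shannon entropy
#' `entropy` (nats) and the uncertainty flag `flagged` (exactly `n_distinct
#' >= 2`, equivalent to H > 0 with no floating tolerance). Names with failed
#' samples are marked `incomplete` and should be excluded from metrics.
#'
#' @param names character vector (or data frame with `raw_name`).
#' @param backend an `rtnomen_backend`.
#' @param k samples per name.
#' @param config a [backend_config()] with temperature > 0; when seeded,
#'   each name gets a distinct, reproducible sub-seed.
#' @return a tibble: `raw_name`, `k`, `n_distinct`, `entropy`, `flagged`,
#'   `incomplete`.
#' @export
uncertainty_profile <- function(names, backend, k = 10,
                                config = backend_config(temperature = 1, top_p = 0.95, seed = 1)) {
  if (is.data.frame(names)) names <- names$raw_name
  names <- as.character(names)
  rows <- purrr::imap(names, function(nm, i) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    s <- sample_predictions(nm, backend, k = k, config = cfg)
    labs <- s$label[s$ok]
    tibble(
      raw_name = nm,
      k = as.integer(k),
      n_distinct = length(unique(labs)),
      entropy = if (length(labs) > 0) shannon_entropy(labs) else NA_real_,
      flagged = length(unique(labs)) >= 2,
      incomplete = isTRUE(attr(s, "incomplete"))
    )
  })
  bind_rows(rows)
}

#' Entropy as a binary error detector
#'
#' Evaluates non-zero entropy as a classifier of renaming errors. The
#' condition positive is an *incorrect* deterministic assignment; the test
#' positive is non-zero sampling entropy (at least two distinct labels).
#' Sensitivity is TP/(TP+FN) over incorrect records, specificity TN/(TN+FP)
#' over correct records, and phi the binary Pearson correlation between the
#' incorrect indicator and the non-zero-entropy indicator. Records marked
#' incomplete are excluded and counted.
#'
#' @param records a data frame with logical `correct` (from the
#'   deterministic, temperature-0 run) and numeric `entropy` columns (or a
#'   logical `flagged` column); optional `incomplete` column.
#' @return an `entropy_metrics` object: list with `phi`
#'   (a `binary_assoc`), `sensitivity`, `specificity`, `counts`
#'   (TP/FN/TN/FP), `n`, `n_excluded`.
#' @export
entropy_error_metrics <- function(records) {
  stopifnot(is.data.frame(records), "correct" %in% names(records))
  if (nrow(records) == 0) {
    abort("entropy_error_metrics() requires at least one record",
      class = "rtnomen_empty_input"
    )
  }
  n_excluded <- 0L
  if ("incomplete" %in% names(records)) {
    n_excluded <- sum(records$incomplete, na.rm = TRUE)
    records <- records[!records$incomplete %in% TRUE, , drop = FALSE]
  }
  flagged <- if ("flagged" %in% names(records)) {
    records$flagged
  } else {
    records$entropy > 0
  }
  incorrect <- !records$correct
  tp <- sum(incorrect & flagged)
  fn <- sum(incorrect & !flagged)
  tn <- sum(!incorrect & !flagged)
  fp <- sum(!incorrect & flagged)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  phi <- if (nrow(records) >= 2) phi_correlation(incorrect, flagged) else NULL
  structure(
    list(
      phi = phi, sensitivity = sens, specificity = spec,
      counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
      n = nrow(records), n_excluded = n_excluded
    ),
    class = "entropy_metrics"
  )
}

#' @export
print.entropy_metrics <- function(x, ...) {
  cat("<entropy_metrics>\n")
  cat(sprintf(
    "  sensitivity %.3f, specificity %.3f, phi %s (n = %d, excluded %d)\n",
    x$sensitivity, x$specificity,
    if (is.null(x$phi) || x$phi$degenerate) "undefined" else sprintf("%.3f", x$phi$phi),
    x$n, x$n_excluded
  ))
  invisible(x)
}

#' Glance at entropy-classifier metrics
#'
#' @param x an [entropy_error_metrics()] result.
#' @param ... unused.
#' @return a one-row tibble with phi, sensitivity, specificity, the
#'   confusion-matrix cells and cohort sizes.
#' @method glance entropy_metrics
#' @export
glance.entropy_metrics <- function(x, ...) {
  tibble(
    phi = if (is.null(x$phi)) NA_real_ else x$phi$phi,
    phi_degenerate = if (is.null(x$phi)) NA else x$phi$degenerate,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    tp = x$counts[["tp"]], fn = x$counts[["fn"]],
    tn = x$counts[["tn"]], fp = x$counts[["fp"]],
    n = x$n, n_excluded = x$n_excluded
  )
}

#' Correlation between self-reported confidence and errors
#'
#' Applies the standard coding — low or medium confidence = 1, high = 0;
#' wrong prediction = 1, correct = 0 — and computes the phi correlation,
#' quantifying how useful self-reported confidence is for flagging errors.
#' Missing confidence (unparseable replies) is conservatively coded as low.
#'
#' @param records a data frame with `confidence` (low/medium/high/missing)
#'   and logical `correct` columns.
#' @return a `binary_assoc` object; degenerate margins (e.g. constant
#'   confidence) yield a flagged undefined value.
#' @export
confidence_error_correlation <- function(records) {
  stopifnot(
    is.data.frame(records),
    all(c("confidence", "correct") %in% names(records))
  )
  low <- records$confidence %in% c("low", "medium", "missing")
  phi_correlation(low, !records$correct)
}
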