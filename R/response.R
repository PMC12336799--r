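# The machine-parseable reply grammar imposed on renaming backends.
#
# A well-formed reply contains, possibly after free-text reasoning, a block
#
#     name: <predicted name or "no match"> | confidence: <low|medium|high>
#
# (the two fields may also sit on consecutive lines). Reasoning models emit
# chain-of-thought before the answer, so the *last* well-formed block wins.

response_block_regex <- function() {
  paste0(
    "name\\s*[:=]\\s*(?<name>[^|\\r\\n]+?)\\s*",
    "(?:\\|\\s*|\\r?\\n\\s*)",
    "confidence\\s*[:=]\\s*(?<conf>low|medium|high)\\b"
  )
}

#' Parse a backend reply into a prediction
#'
#' Extracts the predicted name and confidence from a raw backend reply
#' according to the package's reply grammar, stripping any chain-of-thought
#' preamble (the last well-formed block is used). The textual no-match answer
#' is recognized case-insensitively and mapped to the [no_match()] sentinel.
#' Unparseable replies never raise an error: they yield `parse_ok = FALSE`
#' and `confidence = "missing"`, so batch runs cannot abort on a malformed
#' reply.
#'
#' @param raw character vector of raw reply texts.
#' @param backend_id identifier stored alongside the parsed fields.
#' @return a tibble with columns `predicted_name`, `confidence`
#'   (low/medium/high/missing), `parse_ok`, `raw_response`, `backend_id`.
#' @examples
#' parse_response("name: Kidneys | confidence: high")
#' parse_response("The organ is probably renal.")  # no structured block
#' @export
parse_response <- function(raw, backend_id = NA_character_) {
  rx <- response_block_regex()
  one <- function(txt) {
    if (is.na(txt)) {
      return(list(name = NA_character_, conf = "missing", ok = FALSE))
    }
    m <- gregexpr(rx, txt, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) {
      # tolerate a bare "name:" field with no confidence
      m2 <- gregexpr("name\\s*[:=]\\s*(?<name>[^|\\r\\n]+)", txt,
        perl = TRUE, ignore.case = TRUE
      )[[1]]
      if (m2[1] == -1) {
        return(list(name = NA_character_, conf = "missing", ok = FALSE))
      }
      nm <- last_capture(m2, txt, "name")
      return(list(name = canonical_label(nm), conf = "missing", ok = TRUE))
    }
    nm <- last_capture(m, txt, "name")
    cf <- tolower(last_capture(m, txt, "conf"))
    list(name = canonical_label(nm), conf = cf, ok = TRUE)
  }
  res <- purrr::map(as.character(raw), one)
  tibble(
    predicted_name = purrr::map_chr(res, "name"),
    confidence = purrr::map_chr(res, "conf"),
    parse_ok = purrr::map_lgl(res, "ok"),
    raw_response = as.character(raw),
    backend_id = backend_id
  )
}

# pull one named capture group from the last match of a gregexpr result
last_capture <- function(m, txt, group) {
  k <- length(m)
  starts <- attr(m, "capture.start")[k, group]
  lens <- attr(m, "capture.length")[k, group]
  trimws(substr(txt, starts, starts + lens - 1))
}

#' Render a prediction in the reply grammar
#'
#' Inverse of [parse_response()]: produces a reply string that parses back to
#' the same `(predicted_name, confidence)` pair.
#'
#' @param predicted_name character vector (standard names or [no_match()]).
#' @param confidence one of `"low"`, `"medium"`, `"high"` (vectorized).
#' @return character vector of reply strings.
#' @export
render_response <- function(predicted_name, confidence = "high") {
  shown <- ifelse(is_no_match(predicted_name), "no match", predicted_name)
  paste0("name: ", shown, " | confidence: ", confidence)
}
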