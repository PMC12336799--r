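#' Remote chat-completion backend
#'
#' Sends each renaming prompt to an HTTP endpoint speaking the common
#' chat-completion protocol (`POST {endpoint}/chat/completions` with a JSON
#' body carrying `model`, `messages`, `temperature` and `top_p` taken
#' verbatim from the [backend_config()]). The reply's message content is
#' parsed with [parse_response()], so chain-of-thought text emitted by
#' reasoning models is tolerated. Transport uses the system `curl` binary;
#' failures are retried up to `config$retries` times and then recorded as
#' per-item failure states — a batch run always completes.
#'
#' @param endpoint base URL of the API (without the `/chat/completions`
#'   suffix).
#' @param model model identifier sent in the request body.
#' @param lexicon a [load_lexicon()] object used to build prompts.
#' @param template prompt template file, see [build_prompt()].
#' @param fewshot few-shot example set, see [default_fewshot()].
#' @param api_key optional bearer token.
#' @param timeout per-request timeout in seconds.
#' @return an `rtnomen_backend` object for use with [rename_batch()].
#' @export
backend_remote <- function(endpoint, model, lexicon,
                           template = default_prompt_template(),
                           fewshot = default_fewshot(),
                           api_key = NULL, timeout = 120) {
  stopifnot(inherits(lexicon, "tg263_lexicon"))
  structure(
    list(
      id = paste0("remote:", model),
      endpoint = sub("/+$", "", endpoint),
      model = model,
      lexicon = lexicon,
      template = template,
      fewshot = fewshot,
      api_key = api_key,
      timeout = timeout
    ),
    class = c("rtnomen_backend_remote", "rtnomen_backend")
  )
}

#' @export
predict_backend.rtnomen_backend_remote <- function(backend, name, config) {
  prompt <- build_prompt(name, backend$lexicon,
    template = backend$template, fewshot = backend$fewshot
  )
  body <- jsonlite::toJSON(
    list(
      model = backend$model,
      messages = list(list(role = "user", content = prompt$text)),
      temperature = config$temperature,
      top_p = config$top_p
    ),
    auto_unbox = TRUE
  )
  reply <- NULL
  last_err <- "request failed"
  for (attempt in seq_len(config$retries + 1L)) {
    res <- remote_post(backend, body)
    if (res$ok) {
      reply <- res$text
      break
    }
    last_err <- res$error
  }
  if (is.null(reply)) {
    return(new_prediction(
      raw_name = name, predicted_name = NA_character_, confidence = "missing",
      raw_response = NA_character_, backend_id = backend$id,
      parse_ok = FALSE, error = last_err
    ))
  }
  content <- tryCatch(
    jsonlite::fromJSON(reply)$choices$message$content[[1]],
    error = function(e) reply
  )
  parsed <- parse_response(content, backend_id = backend$id)
  new_prediction(
    raw_name = name, predicted_name = parsed$predicted_name,
    confidence = parsed$confidence, raw_response = content,
    backend_id = backend$id, parse_ok = parsed$parse_ok
  )
}

# one POST via the system curl binary; returns list(ok, text | error)
remote_post <- function(backend, body) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(body, tmp, useBytes = TRUE)
  args <- c(
    "-sS", "--fail-with-body", "--max-time", backend$timeout,
    "-H", "Content-Type: application/json",
    if (!is.null(backend$api_key)) {
      c("-H", paste0("Authorization: Bearer ", backend$api_key))
    },
    "--data-binary", paste0("@", tmp),
    paste0(backend$endpoint, "/chat/completions")
  )
  out <- suppressWarnings(
    tryCatch(
      system2("curl", args, stdout = TRUE, stderr = TRUE),
      error = function(e) structure(conditionMessage(e), status = 127L)
    )
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    list(ok = FALSE, error = paste0(
      "transport error (curl exit ", status, "): ",
      paste(utils::tail(out, 2), collapse = " ")
    ))
  } else {
    list(ok = TRUE, text = paste(out, collapse = "\n"))
  }
}
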