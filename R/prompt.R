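# Five-part renaming prompt: (1) task instructions, (2) language and
# abbreviation rules including the no-match rule, (3) output-format and
# confidence rules, (4) few-shot examples, (5) the TG-263 name list together
# with the single input name. Wording is configuration (a replaceable
# template file), not code.

#' Default prompt part texts
#'
#' The instruction wording used when the template placeholders are filled
#' with defaults. Override any element to tune the prompt without touching
#' code.
#'
#' @return named list with elements `instructions`, `language_rules`,
#'   `output_format`.
#' @export
default_prompt_parts <- function() {
  list(
    instructions = paste(
      "You are renaming radiotherapy structures.",
      "Map the given clinical structure name to exactly one name from the",
      "standardized TG-263 list below."
    ),
    language_rules = paste(
      "Input names may be in English, German, or Dutch and may use",
      "abbreviations and laterality or locality indicators (e.g. left,",
      "right, li, re, bds, superior, inferior, cervical).",
      "If no suitable structure name exists in the list, reply with",
      "\"no match\"."
    ),
    output_format = paste(
      "Answer with a single line of the form",
      "'name: <TG-263 name or no match> | confidence: <low|medium|high>'.",
      "The confidence field reflects how certain you are."
    )
  )
}

#' Default few-shot examples
#'
#' Input/expected-output pairs embedded in the prompt to steer format
#' adherence, covering translation, laterality abbreviation, and the
#' no-match rule.
#'
#' @return a data frame with columns `input` and `output`.
#' @export
default_fewshot <- function() {
  tibble(
    input = c("Niere li", "myelum", "Hart", "Referenzpunkt 1"),
    output = c("Kidney_L", "SpinalCord", "Heart", "no match")
  )
}

#' Path of the bundled prompt template
#'
#' @return file path of the default template, a text file with the named
#'   placeholders `{{instructions}}`, `{{language_rules}}`,
#'   `{{output_format}}`, `{{fewshot_examples}}`, `{{tg263_names}}` and
#'   `{{input_name}}`.
#' @export
default_prompt_template <- function() {
  rtnomen_example("prompt_template.txt")
}

#' Build a renaming prompt for one structure name
#'
#' Renders the five-part prompt: instructions, language rules, output-format
#' rules, few-shot examples, and the full TG-263 standard-name list together
#' with exactly one input name. Rendering is byte-deterministic: identical
#' inputs produce identical text.
#'
#' @param name the single raw structure name to rename.
#' @param lexicon a [load_lexicon()] object supplying the TG-263 name list.
#' @param template path to a template file declaring all six placeholders.
#' @param fewshot data frame of `input`/`output` example pairs.
#' @param parts named list of instruction texts, see [default_prompt_parts()].
#' @return an object of class `rtnomen_prompt`: a list with the `spec`
#'   (all five parts plus the input name) and the rendered `text`.
#' @examples
#' p <- build_prompt("Niere bds", load_lexicon())
#' cat(substr(p$text, 1, 200))
#' @export
build_prompt <- function(name, lexicon,
                         template = default_prompt_template(),
                         fewshot = default_fewshot(),
                         parts = default_prompt_parts()) {
  stopifnot(inherits(lexicon, "tg263_lexicon"), length(name) == 1, nzchar(trimws(name)))
  txt <- paste(readLines(template, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  placeholders <- c(
    "instructions", "language_rules", "output_format",
    "fewshot_examples", "tg263_names", "input_name"
  )
  missing_ph <- placeholders[
    !purrr::map_lgl(placeholders, ~ grepl(paste0("{{", .x, "}}"), txt, fixed = TRUE))
  ]
  if (length(missing_ph) > 0) {
    abort(
      paste0(
        "Prompt template is missing placeholder(s): ",
        paste(paste0("{{", missing_ph, "}}"), collapse = ", ")
      ),
      class = "rtnomen_template_error"
    )
  }
  fewshot_txt <- paste0(
    "Input: ", fewshot$input, "\nOutput: name: ", fewshot$output,
    " | confidence: high",
    collapse = "\n\n"
  )
  values <- list(
    instructions = parts$instructions,
    language_rules = parts$language_rules,
    output_format = parts$output_format,
    fewshot_examples = fewshot_txt,
    tg263_names = paste(lexicon$entries$standard_name, collapse = "\n"),
    input_name = trimws(name)
  )
  rendered <- txt
  for (ph in placeholders) {
    rendered <- gsub(paste0("{{", ph, "}}"), values[[ph]], rendered, fixed = TRUE)
  }
  structure(
    list(
      spec = c(values[setdiff(placeholders, "tg263_names")],
        list(tg263_names = lexicon$entries$standard_name)
      ),
      text = rendered
    ),
    class = "rtnomen_prompt"
  )
}

#' @export
print.rtnomen_prompt <- function(x, ...) {
  cat("<rtnomen_prompt> for input '", x$spec$input_name, "' (",
    nchar(x$text), " characters)\n",
    sep = ""
  )
  invisible(x)
}
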