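#' Prompt specification
#'
#' Word-level anatomical prompts drive the text-guided detector. Two framing
#' styles are supported: `"plain"` joins the terms with `". "` (a single term
#' stays as-is, e.g. `"right lung"`), and `"dot_separated"` emits every
#' whitespace token followed by `" . "`-style separators, e.g.
#' `"right . lung ."` — the punctuation-delimited framing that keeps each
#' word an independent token for the detector's text encoder.
#'
#' @param raw_terms Character vector of anatomical terms, e.g.
#'   `c("right lung")`; each must be nonempty after trimming.
#' @param style `"plain"` (default) or `"dot_separated"`.
#' @param case_mode `"as_given"` (default), `"lower"`, or `"upper"`; applied
#'   last.
#' @param sentence_level Metadata flag marking free-form sentence prompts
#'   (e.g. "segment the right lobe"), which are passed through verbatim and
#'   reported separately.
#' @return A `prompt_spec` object.
#' @export
prompt_spec <- function(raw_terms,
                        style = c("plain", "dot_separated"),
                        case_mode = c("as_given", "lower", "upper"),
                        sentence_level = FALSE) {
  style <- match.arg(style)
  case_mode <- match.arg(case_mode)
  raw_terms <- as.character(raw_terms)
  if (length(raw_terms) == 0L) stop("`raw_terms` must be nonempty")
  if (any(!nzchar(trimws(raw_terms)))) {
    stop("every term must be nonempty after trimming")
  }
  structure(list(raw_terms = trimws(raw_terms), style = style,
                 case_mode = case_mode, sentence_level = sentence_level),
            class = "prompt_spec")
}

#' Build the prompt text from a specification
#'
#' @param spec A [prompt_spec()].
#' @return A single prompt string.
#' @examples
#' build_prompt(prompt_spec("right lung"))                       # "right lung"
#' build_prompt(prompt_spec("right lung", style = "dot_separated"))
#' # "right . lung ."
#' @export
build_prompt <- function(spec) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (spec$sentence_level || spec$style == "plain") {
    out <- paste(spec$raw_terms, collapse = ". ")
  } else {
    tokens <- unlist(strsplit(spec$raw_terms, "\\s+"))
    tokens <- tokens[nzchar(tokens)]
    out <- paste(paste(tokens, collapse = " . "), ".")
  }
  switch(spec$case_mode,
         as_given = out,
         lower = tolower(out),
         upper = toupper(out))
}

#' Extract anatomical tokens from a prompt
#'
#' Lowercases, strips dot separators, and returns the word tokens. Used by
#' backends and reporting to recognise the side (`left`/`right`) and anatomy
#' (`lung`/`lobe`) named by a prompt via simple token containment.
#'
#' @param prompt Prompt string.
#' @return Character vector of lowercase tokens.
#' @export
prompt_tokens <- function(prompt) {
  tokens <- unlist(strsplit(tolower(prompt), "[.[:space:]]+"))
  tokens[nzchar(tokens)]
}

#' Side named by a prompt
#' @param prompt Prompt string.
#' @return `"right"`, `"left"`, or `NA` when no side token is present.
#' @export
prompt_side <- function(prompt) {
  tokens <- prompt_tokens(prompt)
  sides <- intersect(c("right", "left"), tokens)
  if (length(sides) == 0L) NA_character_ else sides[[1]]
}

#' Load prompt specifications from a YAML file
#'
#' The file holds a list of entries with fields `raw_terms` (string or list),
#' and optional `style`, `case_mode`, `sentence_level`.
#'
#' @param path YAML file.
#' @return List of [prompt_spec()] objects.
#' @export
read_prompts_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  lapply(entries, function(e) {
    if (is.character(e)) return(prompt_spec(e))
    prompt_spec(raw_terms = unlist(e$raw_terms),
                style = if (is.null(e$style)) "plain" else e$style,
                case_mode = if (is.null(e$case_mode)) "as_given" else e$case_mode,
                sentence_level = isTRUE(e$sentence_level))
  })
}
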