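#' Break a summary into bullets for fact-checking
#'
#' One bullet per segmented sentence; citation brackets are retained so the
#' model can line each claim up with its cited source.
#'
#' @param summary Non-empty summary text.
#' @return Character vector of bullet strings.
#' @export
split_bullets <- function(summary) {
  stopifnot(is.character(summary), length(summary) == 1)
  if (!nzchar(trimws(summary))) {
    stop("split_bullets: empty summary", call. = FALSE)
  }
  segment_sentences(summary)
}

#' Parse true/false verdict lines from a fact-check response
#'
#' The consistency-check template asks for one line per bullet of the form
#' `"<index>. TRUE - <explanation>"`. Parsing is tolerant: case-insensitive
#' verdicts, flexible separators (`.`/`)`/`:` after the index, `-`, en/em
#' dashes or `:` before the explanation). Anything that cannot be parsed —
#' a missing index, a malformed line, or a TRUE/FALSE verdict with an empty
#' explanation — degrades to `UNPARSEABLE`, which counts as a failure
#' (fail-closed): a verdict the pipeline cannot read must trigger revision,
#' never silently pass.
#'
#' @param response Raw model response text.
#' @param n_bullets Number of bullets the verdicts must cover.
#' @return An object of class `consistency_report`: a list with `verdicts`
#'   (data.frame: `index`, `verdict`, `explanation`), `any_false`, and
#'   `raw_response`.
#' @export
parse_verdicts <- function(response, n_bullets) {
  stopifnot(n_bullets >= 1)
  verdicts <- data.frame(index = seq_len(n_bullets),
                         verdict = rep("UNPARSEABLE", n_bullets),
                         explanation = rep("", n_bullets),
                         stringsAsFactors = FALSE)
  lines <- strsplit(response %||% "", "\n")[[1]]
  pat <- "^\\s*([0-9]+)\\s*[.):]?\\s*(true|false)\\b[\\s:\\-–—]*(.*)$"
  for (line in lines) {
    m <- regmatches(line, regexec(pat, line, ignore.case = TRUE, perl = TRUE))[[1]]
    if (length(m) == 0) next
    idx <- as.integer(m[2])
    if (is.na(idx) || idx < 1 || idx > n_bullets) next
    expl <- trimws(m[4])
    if (!nzchar(expl)) next # TRUE/FALSE without explanation stays UNPARSEABLE
    verdicts$verdict[idx] <- toupper(m[3])
    verdicts$explanation[idx] <- expl
  }
  any_false <- any(verdicts$verdict %in% c("FALSE", "UNPARSEABLE"))
  structure(list(verdicts = verdicts, any_false = any_false,
                 raw_response = response),
            class = "consistency_report")
}

#' Self-consistency check with one revision round
#'
#' Splits the summary into bullets, asks the backend for per-bullet
#' true/false verdicts with explanations against the context, and — iff any
#' bullet is judged false or unparseable — makes exactly one revision call
#' feeding back the summary, the flagged verdict lines, and the context.
#' The module never edits summary text itself: every change to the summary
#' comes from the backend, so provenance stays intact. The caller is
#' responsible for re-running the final reference check on a revised
#' summary.
#'
#' @param summary Summary text (expected to have passed reference checks).
#' @param context A `summary_context`.
#' @param backend An LLM backend.
#' @param params A [generation_params()]; defaults to the conservative
#'   checking parameters.
#' @param budget A [token_budget()].
#' @param counter Token-counter backend.
#' @param template_dir Optional template directory override.
#' @return A list with `report` (`consistency_report`), `summary` (revised or
#'   unchanged), and `revised` (logical).
#' @export
consistency_pass <- function(summary, context, backend,
                             params = conservative_params(),
                             budget = token_budget(), counter = "words",
                             template_dir = NULL) {
  bullets <- split_bullets(summary)
  numbered <- paste(sprintf("%d. %s", seq_along(bullets), bullets),
                    collapse = "\n")
  check_prompt <- render_prompt(
    load_template("consistency_check", dir = template_dir),
    list(bullets = numbered, context = format_context(context)))
  response <- llm_complete(backend, "consistency_check", check_prompt, params,
                           budget = budget, counter = counter)
  report <- parse_verdicts(response, length(bullets))

  if (!report$any_false) {
    return(list(report = report, summary = summary, revised = FALSE))
  }
  flagged <- report$verdicts[report$verdicts$verdict != "TRUE", , drop = FALSE]
  issues <- paste(sprintf("%d. %s - %s", flagged$index, flagged$verdict,
                          ifelse(nzchar(flagged$explanation),
                                 flagged$explanation,
                                 "verdict could not be parsed")),
                  collapse = "\n")
  revise_prompt <- render_prompt(
    load_template("consistency_revise", dir = template_dir),
    list(summary = summary, issues = issues,
         context = format_context(context)))
  revised <- llm_complete(backend, "consistency_revise", revise_prompt,
                          params, budget = budget, counter = counter)
  list(report = report, summary = revised, revised = TRUE)
}
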