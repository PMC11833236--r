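#' Count tokens in a text
#'
#' Token accounting drives every budget decision in the pipeline: context
#' assembly, prompt-window guards, and usage logging. Two deterministic
#' backends are provided behind a common interface, and any function
#' `text -> integer` can be supplied instead:
#'
#' * `"words"` (default): the rule-of-thumb estimator, one token per 0.75
#'   words, i.e. `ceiling(word_count / 0.75)`.
#' * `"subword"`: a length-based subword heuristic closer to how BPE
#'   vocabularies fragment English prose — each punctuation mark is one
#'   token and each word contributes `ceiling(nchar / 4)` tokens.
#'
#' @param text A single string.
#' @param backend `"words"`, `"subword"`, or a function of one argument.
#' @return A non-negative integer token count.
#' @examples
#' count_tokens("")                    # 0
#' count_tokens("three short words")   # 4
#' @export
count_tokens <- function(text, backend = c("words", "subword")) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.function(backend)) return(as.integer(backend(text)))
  backend <- match.arg(backend)
  if (!nzchar(trimws(text))) return(0L)
  words <- regmatches(text, gregexpr("\\S+", text))[[1]]
  if (backend == "words") {
    return(as.integer(ceiling(length(words) / 0.75)))
  }
  # subword: punctuation marks are single tokens; words fragment into
  # 8-character chunks (English BPE averages ~1.3 tokens per word).
  toks <- regmatches(text, gregexpr("[[:alnum:]]+(?:[-'][[:alnum:]]+)*|[^[:alnum:][:space:]]", text))[[1]]
  total <- 0L
  for (t in toks) {
    if (grepl("^[[:alnum:]]", t)) {
      total <- total + as.integer(ceiling(nchar(t) / 8))
    } else {
      total <- total + 1L
    }
  }
  total
}

# Vectorised helper used when filling token counts on a corpus.
count_tokens_many <- function(texts, backend = "words") {
  vapply(texts, count_tokens, integer(1), backend = backend, USE.NAMES = FALSE)
}

#' Token budget for context construction
#'
#' Encodes how the model window is partitioned. With a 4096-token window, the
#' literature context is capped at 2560 tokens (about 1920 words) so the
#' remainder covers the prompt text (60-140 tokens), the generated summary
#' (about 255 tokens), and a later revision round (about 1150 tokens).
#'
#' @param model_window Total model context window, tokens.
#' @param context_limit Maximum tokens of literature sentences in a context.
#' @param reserved_output Tokens reserved for the generated summary.
#' @param reserved_prompt Tokens reserved for prompt text (upper bound).
#' @param reserved_revision Tokens reserved for the revision round.
#' @param slack Documented allowance by which the reservations may exceed the
#'   window (the revision reservation is only consumed in a separate call).
#' @return An object of class `token_budget`.
#' @export
token_budget <- function(model_window = 4096L, context_limit = 2560L,
                         reserved_output = 255L, reserved_prompt = 140L,
                         reserved_revision = 1150L, slack = 1300L) {
  stopifnot(context_limit < model_window)
  total <- context_limit + reserved_output + reserved_prompt + reserved_revision
  if (total > model_window + slack) {
    stop("token_budget: reservations exceed model window plus documented slack",
         call. = FALSE)
  }
  structure(
    list(model_window = as.integer(model_window),
         context_limit = as.integer(context_limit),
         reserved_output = as.integer(reserved_output),
         reserved_prompt = as.integer(reserved_prompt),
         reserved_revision = as.integer(reserved_revision),
         slack = as.integer(slack)),
    class = "token_budget"
  )
}
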