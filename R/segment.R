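#' Sentence segmentation
#'
#' Rule-based sentence splitter: a sentence boundary is a run of `.`, `!`, or
#' `?` followed by whitespace and an uppercase letter or digit, unless the
#' preceding token is a guarded abbreviation (`"Fig."`, `"et al."`, `"e.g."`,
#' ...). Blank lines always terminate a sentence. The segmenter is the single
#' convention used across the package: mention extraction, citation placement,
#' adequacy ratios, and bullet decomposition all count sentences the same way.
#'
#' `segment_spans()` returns character offsets into the original text so
#' callers can map entities (e.g. citation instances) back onto sentences;
#' `segment_sentences()` returns the cleaned sentence strings (internal
#' whitespace collapsed, so sentences never contain newlines).
#'
#' @param text A single string.
#' @param abbreviations Character vector of lower-case abbreviation tails that
#'   must not end a sentence.
#' @return `segment_spans()`: a data.frame with columns `start`, `end`
#'   (inclusive 1-based offsets) and `text`. `segment_sentences()`: a
#'   character vector.
#' @examples
#' segment_sentences("Expression rose (Fig. 2). It fell later.")
#' @export
segment_spans <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  n <- nchar(text)
  breaks <- integer() # last character index of each sentence

  # Terminal punctuation followed by whitespace + uppercase/digit.
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[[:upper:][:digit:]])", text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      end_pos <- m[i] + lens[i] - 1L
      tail <- tolower(substr(text, max(1L, m[i] - 11L), end_pos))
      guarded <- any(vapply(abbreviations, function(a) endsWith(tail, a), logical(1)))
      if (!guarded) breaks <- c(breaks, end_pos)
    }
  }
  # Blank lines force a boundary at the last non-space char before them.
  pb <- gregexpr("\n[ \t]*\n", text, perl = TRUE)[[1]]
  if (pb[1] != -1) {
    for (p in pb) {
      j <- p - 1L
      while (j >= 1L && grepl("[ \t\r]", substr(text, j, j))) j <- j - 1L
      if (j >= 1L) breaks <- c(breaks, j)
    }
  }
  breaks <- sort(unique(c(breaks, n)))

  starts <- c(1L, head(breaks, -1L) + 1L)
  spans <- data.frame(start = starts, end = breaks, stringsAsFactors = FALSE)
  spans$text <- vapply(seq_len(nrow(spans)), function(i) {
    s <- substr(text, spans$start[i], spans$end[i])
    trimws(gsub("[[:space:]]+", " ", s))
  }, character(1))
  spans[nzchar(spans$text), , drop = FALSE]
}

#' @rdname segment_spans
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  segment_spans(text, abbreviations)$text
}

#' @rdname segment_spans
#' @export
default_abbreviations <- function() {
  c("fig.", "figs.", "et al.", " al.", "e.g.", "i.e.", "cf.", "vs.",
    "ca.", "approx.", "no.", "nos.", "dr.", "st.", "resp.")
}

# Index of the sentence span containing character position `pos` (the last
# span whose start is <= pos); 0 if before all spans.
span_index_at <- function(spans, pos) {
  if (nrow(spans) == 0) return(0L)
  idx <- which(spans$start <= pos & spans$end >= pos)
  if (length(idx) > 0) return(idx[1])
  idx <- which(spans$start <= pos)
  if (length(idx) == 0) 0L else max(idx)
}
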