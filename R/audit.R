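#' Thresholds for the reference checks
#'
#' @param min_refs_per_sentence Minimum references per sentence for the
#'   adequacy check (0.5: at least one reference per two sentences).
#' @param max_fraction_per_instance Largest share of all references one
#'   citation instance may hold (0.5: no more than half).
#' @param min_total_for_concentration Below this many total references the
#'   concentration check is vacuously satisfied — a literal 50% rule would
#'   reject every single-citation summary.
#' @param max_nonterminal_fraction Tolerated share of citation instances not
#'   at a sentence end ("usually at the end of sentences").
#' @param bracket_mode `"strict"` treats parenthesized citations like
#'   `(PMC1)` as a formatting failure; `"lenient"` accepts them.
#' @return An object of class `check_thresholds`.
#' @export
check_thresholds <- function(min_refs_per_sentence = 0.5,
                             max_fraction_per_instance = 0.5,
                             min_total_for_concentration = 3L,
                             max_nonterminal_fraction = 0.2,
                             bracket_mode = c("strict", "lenient")) {
  stopifnot(min_refs_per_sentence > 0, min_refs_per_sentence <= 1,
            max_fraction_per_instance > 0, max_fraction_per_instance <= 1)
  structure(
    list(min_refs_per_sentence = min_refs_per_sentence,
         max_fraction_per_instance = max_fraction_per_instance,
         min_total_for_concentration = as.integer(min_total_for_concentration),
         max_nonterminal_fraction = max_nonterminal_fraction,
         bracket_mode = match.arg(bracket_mode)),
    class = "check_thresholds"
  )
}

new_check_report <- function(check, passed, detail = list()) {
  structure(
    list(check = check, passed = passed, detail = detail,
         rescue_template = if (passed) NULL else rescue_for_check(check)),
    class = "check_report"
  )
}

#' Parse citation instances from a summary
#'
#' A citation instance is either a bracketed group containing one or more
#' well-formed PMCIDs (`[PMC1]`, `[PMC1, PMC2]`) or a bare `PMC<digits>`
#' token. Bracketed groups with no valid PMCID (e.g. `[PMCabc]`, `[1]`)
#' yield no instance — the formatting check flags them. Each instance records
#' its character span, the sentence it falls in (package segmenter), and
#' whether it abuts that sentence's end (only whitespace, punctuation, or
#' other citations may follow it).
#'
#' @param summary A summary string.
#' @return A data.frame with one row per instance: `start`, `end` (1-based
#'   inclusive), `sentence_index`, `terminal`, and list-column `pmcids`.
#' @export
parse_citations <- function(summary) {
  stopifnot(is.character(summary), length(summary) == 1)
  spans <- segment_spans(summary)
  starts <- integer(); ends <- integer(); pmcids <- list()

  bm <- gregexpr("\\[[^][]*\\]", summary)[[1]]
  bracket_spans <- NULL
  if (bm[1] != -1) {
    blens <- attr(bm, "match.length")
    for (i in seq_along(bm)) {
      content <- substr(summary, bm[i] + 1L, bm[i] + blens[i] - 2L)
      ids <- regmatches(content, gregexpr("PMC[0-9]+", content))[[1]]
      if (length(ids) > 0) {
        starts <- c(starts, bm[i])
        ends <- c(ends, bm[i] + blens[i] - 1L)
        pmcids <- c(pmcids, list(ids))
      }
    }
    bracket_spans <- cbind(bm, bm + blens - 1L)
  }

  # Bare PMC tokens outside any bracket group.
  tm <- gregexpr("PMC[0-9]+", summary)[[1]]
  if (tm[1] != -1) {
    tlens <- attr(tm, "match.length")
    for (i in seq_along(tm)) {
      s <- tm[i]; e <- tm[i] + tlens[i] - 1L
      inside <- !is.null(bracket_spans) &&
        any(bracket_spans[, 1] <= s & bracket_spans[, 2] >= e)
      if (!inside) {
        starts <- c(starts, s)
        ends <- c(ends, e)
        pmcids <- c(pmcids, list(substr(summary, s, e)))
      }
    }
  }

  if (length(starts) == 0) {
    out <- data.frame(start = integer(), end = integer(),
                      sentence_index = integer(), terminal = logical(),
                      stringsAsFactors = FALSE)
    out$pmcids <- list()
    return(out)
  }
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; pmcids <- pmcids[ord]

  sentence_index <- vapply(starts, function(s) span_index_at(spans, s),
                           integer(1))
  terminal <- vapply(seq_along(starts), function(i) {
    si <- sentence_index[i]
    if (si == 0) return(FALSE)
    tail_start <- ends[i] + 1L
    tail_end <- spans$end[si]
    if (tail_start > tail_end) return(TRUE)
    # Blank out other citation instances in the tail, then require only
    # whitespace/punctuation.
    tail_chars <- strsplit(substr(summary, tail_start, tail_end), "")[[1]]
    for (j in seq_along(starts)) {
      if (j == i) next
      ov <- intersect(seq(starts[j], ends[j]), seq(tail_start, tail_end))
      if (length(ov) > 0) tail_chars[ov - tail_start + 1L] <- " "
    }
    grepl("^[][ \t\r\n.!?,;()]*$", paste(tail_chars, collapse = ""))
  }, logical(1))

  out <- data.frame(start = starts, end = ends,
                    sentence_index = sentence_index, terminal = terminal,
                    stringsAsFactors = FALSE)
  out$pmcids <- pmcids
  out
}

#' The five reference checks
#'
#' Each check inspects one failure mode of a generated summary and returns a
#' `check_report` with a machine-readable detail payload and, on failure, the
#' rescue template that addresses it:
#'
#' * **adequacy** — at least `min_refs_per_sentence` references per sentence
#'   (references counted with multiplicity);
#' * **formatting** — every citation-like token must be a well-formed
#'   bracketed PMCID group (numeric markers, PMIDs, DOIs, malformed ids, and
#'   — in strict mode — parenthesized groups all fail);
#' * **realness** — every cited PMCID must occur in the context (catches
#'   invented identifiers);
#' * **placement** — citations belong at sentence ends: fail when all
#'   instances trail the prose, or when more than
#'   `max_nonterminal_fraction` of them sit mid-sentence;
#' * **concentration** — no single citation instance may hold more than
#'   `max_fraction_per_instance` of all references (vacuous below
#'   `min_total_for_concentration` total references).
#'
#' @param summary Summary text.
#' @param instances Result of [parse_citations()] on `summary`.
#' @param thresholds A [check_thresholds()].
#' @param context A `summary_context` (for realness).
#' @return A `check_report` object.
#' @export
check_adequacy <- function(summary, instances,
                           thresholds = check_thresholds()) {
  n_sentences <- length(segment_sentences(summary))
  if (n_sentences == 0) {
    stop("check_adequacy: summary has no sentences", call. = FALSE)
  }
  n_refs <- sum(vapply(instances$pmcids, length, integer(1)))
  ratio <- n_refs / n_sentences
  new_check_report("adequacy",
                   passed = ratio >= thresholds$min_refs_per_sentence,
                   detail = list(ratio = ratio, n_refs = n_refs,
                                 n_sentences = n_sentences))
}

#' @rdname check_adequacy
#' @export
check_formatting <- function(summary, instances,
                             thresholds = check_thresholds()) {
  offending <- character()

  bm <- gregexpr("\\[[^][]*\\]", summary)[[1]]
  if (bm[1] != -1) {
    blens <- attr(bm, "match.length")
    for (i in seq_along(bm)) {
      grp <- substr(summary, bm[i], bm[i] + blens[i] - 1L)
      content <- substr(grp, 2, nchar(grp) - 1)
      ok <- grepl("^\\s*PMC[0-9]+(\\s*[,;]\\s*PMC[0-9]+|\\s+PMC[0-9]+)*\\s*$",
                  content)
      if (!ok) offending <- c(offending, grp)
    }
  }
  if (grepl("\\bPMID\\b", summary, ignore.case = TRUE)) {
    offending <- c(offending, "PMID")
  }
  if (grepl("\\bdoi\\b", summary, ignore.case = TRUE)) {
    offending <- c(offending, "doi")
  }
  if (thresholds$bracket_mode == "strict" &&
      grepl("\\(\\s*PMC[0-9]", summary)) {
    offending <- c(offending, "(PMC...)")
  }
  # Bare PMC tokens with trailing letters (e.g. PMC12a) are malformed ids.
  if (grepl("PMC[0-9]+[A-Za-z]", summary)) {
    offending <- c(offending, "PMC<digits><letters>")
  }
  new_check_report("formatting", passed = length(offending) == 0,
                   detail = list(offending = offending))
}

#' @rdname check_adequacy
#' @export
check_realness <- function(instances, context) {
  cited <- unique(unlist(instances$pmcids))
  known <- unique(context$sentences$pmcid)
  offending <- setdiff(cited, known)
  new_check_report("realness", passed = length(offending) == 0,
                   detail = list(offending = offending))
}

#' @rdname check_adequacy
#' @export
check_placement <- function(instances, summary,
                            thresholds = check_thresholds()) {
  n <- nrow(instances)
  if (n == 0) {
    return(new_check_report("placement", passed = TRUE,
                            detail = list(n_instances = 0L)))
  }
  # A trailing block is the failure mode where every citation sits after the
  # prose, *behind* a sentence terminator — as opposed to a citation that
  # ends the still-open final sentence, which is where citations belong.
  chars <- strsplit(summary, "")[[1]]
  in_instance <- rep(FALSE, length(chars))
  for (i in seq_len(n)) {
    in_instance[seq(instances$start[i], instances$end[i])] <- TRUE
  }
  prose <- !in_instance & !grepl("[][ \t\r\n.!?,;:()]", chars)
  prose_end <- if (any(prose)) max(which(prose)) else 0L
  all_trailing <- all(instances$start > prose_end)
  if (all_trailing && prose_end > 0) {
    lo <- prose_end + 1L
    hi <- min(instances$start) - 1L
    gap <- if (lo > hi) "" else paste(chars[lo:hi], collapse = "")
    all_trailing <- grepl("[.!?]", gap)
  }

  frac_nonterminal <- mean(!instances$terminal)
  passed <- !all_trailing &&
    frac_nonterminal <= thresholds$max_nonterminal_fraction
  new_check_report("placement", passed = passed,
                   detail = list(all_trailing = all_trailing,
                                 frac_nonterminal = frac_nonterminal,
                                 n_instances = n))
}

#' @rdname check_adequacy
#' @export
check_concentration <- function(instances,
                                thresholds = check_thresholds()) {
  sizes <- vapply(instances$pmcids, length, integer(1))
  total <- sum(sizes)
  if (total < thresholds$min_total_for_concentration) {
    return(new_check_report("concentration", passed = TRUE,
                            detail = list(total = total, exempt = TRUE)))
  }
  biggest <- max(sizes)
  passed <- biggest <= thresholds$max_fraction_per_instance * total
  new_check_report("concentration", passed = passed,
                   detail = list(total = total, max_instance = biggest,
                                 offending_instance = which.max(sizes),
                                 exempt = FALSE))
}

#' Run the five reference checks in order
#'
#' Checks run in the fixed order adequacy, formatting, realness, placement,
#' concentration. The aggregate passes iff all five pass; on failure the
#' rescue template of the *first* failing check is selected.
#'
#' @param summary Summary text.
#' @param context A `summary_context`.
#' @param thresholds A [check_thresholds()].
#' @return A list with `reports` (named list of five `check_report`s),
#'   `passed` (logical), `first_failure` (check name or `NA`), and
#'   `rescue_template` (template name or `NA`).
#' @export
run_reference_checks <- function(summary, context,
                                 thresholds = check_thresholds()) {
  instances <- parse_citations(summary)
  reports <- list(
    adequacy = check_adequacy(summary, instances, thresholds),
    formatting = check_formatting(summary, instances, thresholds),
    realness = check_realness(instances, context),
    placement = check_placement(instances, summary, thresholds),
    concentration = check_concentration(instances, thresholds)
  )
  failed <- names(reports)[!vapply(reports, function(r) r$passed, logical(1))]
  list(reports = reports,
       passed = length(failed) == 0,
       first_failure = if (length(failed) == 0) NA_character_ else failed[1],
       rescue_template = if (length(failed) == 0) NA_character_ else
         reports[[failed[1]]]$rescue_template)
}

#' Serialize an audit result to JSON
#'
#' @param audit Result of [run_reference_checks()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
audit_to_json <- function(audit, path = NULL) {
  obj <- list(
    passed = audit$passed,
    first_failure = audit$first_failure,
    rescue_template = audit$rescue_template,
    checks = lapply(audit$reports, function(r) {
      list(check = r$check, passed = r$passed, detail = r$detail,
           rescue_template = r$rescue_template)
    })
  )
  js <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
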