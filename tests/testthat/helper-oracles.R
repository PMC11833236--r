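# Independent brute-force re-implementations of the reference checks,
# written against the raw summary string with plain regex scans and set
# arithmetic. They deliberately share no code with the package internals.

oracle_citation_spans <- function(summary) {
  spans <- list()
  bm <- gregexpr("\\[[^][]*\\]", summary)[[1]]
  if (bm[1] != -1) {
    for (i in seq_along(bm)) {
      len <- attr(bm, "match.length")[i]
      grp <- substr(summary, bm[i], bm[i] + len - 1)
      ids <- regmatches(grp, gregexpr("PMC[0-9]+", grp))[[1]]
      if (length(ids) > 0) {
        spans[[length(spans) + 1]] <- list(start = bm[i],
                                           end = bm[i] + len - 1, ids = ids)
      }
    }
  }
  tm <- gregexpr("PMC[0-9]+", summary)[[1]]
  if (tm[1] != -1) {
    for (i in seq_along(tm)) {
      len <- attr(tm, "match.length")[i]
      s <- tm[i]; e <- tm[i] + len - 1
      in_bracket <- any(vapply(spans, function(sp) sp$start <= s && sp$end >= e,
                               logical(1)))
      if (!in_bracket) {
        spans[[length(spans) + 1]] <- list(start = s, end = e,
                                           ids = substr(summary, s, e))
      }
    }
  }
  spans[order(vapply(spans, function(sp) sp$start, numeric(1)))]
}

oracle_sentence_count <- function(summary) {
  length(gregexpr("[.!?]+(?=\\s|$)", summary, perl = TRUE)[[1]]) -
    (gregexpr("[.!?]+(?=\\s|$)", summary, perl = TRUE)[[1]][1] == -1)
}

oracle_adequacy <- function(summary) {
  spans <- oracle_citation_spans(summary)
  refs <- sum(vapply(spans, function(sp) length(sp$ids), integer(1)))
  n <- oracle_sentence_count(summary)
  refs / max(n, 1) >= 0.5
}

oracle_formatting <- function(summary) {
  groups <- regmatches(summary, gregexpr("\\[[^][]*\\]", summary))[[1]]
  for (grp in groups) {
    toks <- strsplit(gsub("^\\[|\\]$", "", grp), "[,; ]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0 || !all(grepl("^PMC[0-9]+$", toks))) return(FALSE)
  }
  if (grepl("PMID", summary, ignore.case = TRUE)) return(FALSE)
  if (grepl("\\bdoi\\b", summary, ignore.case = TRUE)) return(FALSE)
  if (grepl("\\(\\s*PMC[0-9]", summary)) return(FALSE)
  if (grepl("PMC[0-9]+[A-Za-z]", summary)) return(FALSE)
  TRUE
}

oracle_realness <- function(summary, context_pmcids) {
  cited <- unique(unlist(lapply(oracle_citation_spans(summary),
                                function(sp) sp$ids)))
  length(setdiff(cited, context_pmcids)) == 0
}

oracle_placement <- function(summary, tol = 0.2) {
  spans <- oracle_citation_spans(summary)
  if (length(spans) == 0) return(TRUE)
  # Mask citations, then reason over the masked string.
  masked <- strsplit(summary, "")[[1]]
  for (sp in spans) masked[sp$start:sp$end] <- " "
  masked <- paste(masked, collapse = "")
  alnum_pos <- gregexpr("[[:alnum:]]", masked)[[1]]
  prose_end <- if (alnum_pos[1] == -1) 0 else max(alnum_pos)
  starts <- vapply(spans, function(sp) sp$start, numeric(1))
  all_trailing <- all(starts > prose_end)
  if (all_trailing && prose_end > 0) {
    gap <- substr(masked, prose_end + 1, max(min(starts) - 1, prose_end))
    all_trailing <- grepl("[.!?]", gap)
  }
  terminal <- vapply(spans, function(sp) {
    tail <- substr(masked, sp$end + 1, nchar(masked))
    nxt <- regexpr("[[:alnum:]]", tail)
    if (nxt == -1) return(TRUE)
    grepl("[.!?]", substr(tail, 1, nxt - 1))
  }, logical(1))
  !all_trailing && mean(!terminal) <= tol
}

oracle_concentration <- function(summary) {
  sizes <- vapply(oracle_citation_spans(summary),
                  function(sp) length(sp$ids), integer(1))
  total <- sum(sizes)
  if (total < 3) return(TRUE)
  max(sizes) <= total / 2
}

oracle_all_checks <- function(summary, context_pmcids) {
  c(adequacy = oracle_adequacy(summary),
    formatting = oracle_formatting(summary),
    realness = oracle_realness(summary, context_pmcids),
    placement = oracle_placement(summary),
    concentration = oracle_concentration(summary))
}

# Naive greedy min-max-cosine trace, plain loops over the raw vectors.
oracle_greedy_trace <- function(vectors, candidates, seed_idx, tokens, limit) {
  cos <- function(a, b) {
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  if (tokens[seed_idx] > limit) return(integer())
  sel <- seed_idx
  used <- tokens[seed_idx]
  rest <- setdiff(candidates, seed_idx)
  while (length(rest) > 0) {
    best <- NA; best_val <- Inf
    for (j in sort(rest)) {
      worst <- -Inf
      for (i in sel) worst <- max(worst, cos(vectors[i, ], vectors[j, ]))
      if (worst < best_val) { best_val <- worst; best <- j }
    }
    if (used + tokens[best] > limit) break
    sel <- c(sel, best)
    used <- used + tokens[best]
    rest <- setdiff(rest, best)
  }
  sel
}
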