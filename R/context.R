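#' Token-budgeted literature context
#'
#' The ordered set of sentences fed to the model as its only source of facts,
#' together with selection provenance: the strategy that produced it, the
#' recomputed token total, and (when topic selection ran) the per-sentence
#' cluster labels.
#'
#' @name summary_context
#' @keywords internal
NULL

new_context <- function(rna_id, sentences, strategy, counter = "words",
                        cluster_labels = NULL, degenerate = FALSE,
                        seed = NA_integer_) {
  total <- if (nrow(sentences) == 0) 0L else sum(sentences$token_count)
  structure(
    list(rna_id = rna_id,
         sentences = sentences,
         total_tokens = as.integer(total),
         strategy = strategy,
         cluster_labels = cluster_labels,
         degenerate = degenerate,
         counter = counter,
         seed = as.integer(seed)),
    class = "summary_context"
  )
}

#' @export
print.summary_context <- function(x, ...) {
  cat(sprintf("<summary_context> %s: %d sentences, %d tokens, strategy=%s\n",
              x$rna_id, nrow(x$sentences), x$total_tokens, x$strategy))
  invisible(x)
}

prepare_corpus <- function(corpus, counter) {
  stopifnot(is.data.frame(corpus),
            all(c("rna_id", "pmcid", "sentence") %in% names(corpus)))
  if (nrow(corpus) > 0 && length(unique(corpus$rna_id)) > 1) {
    stop("select_context: corpus mixes rna_ids: ",
         paste(unique(corpus$rna_id), collapse = ", "), call. = FALSE)
  }
  corpus <- corpus[!duplicated(corpus[, c("pmcid", "sentence")]), , drop = FALSE]
  rownames(corpus) <- NULL
  if (is.null(corpus$token_count) || anyNA(corpus$token_count)) {
    corpus$token_count <- count_tokens_many(corpus$sentence, backend = counter)
  }
  corpus
}

#' Select a token-budgeted context from a sentence corpus
#'
#' Dispatches between the four selection regimes:
#'
#' 1. fewer than `min_sentences` sentences: nothing is summarized
#'    (`strategy = "skipped_too_few"`, empty context);
#' 2. the whole corpus fits the token cap: no selection
#'    (`strategy = "all"`);
#' 3. over budget but topic clustering inapplicable (too few sentences for
#'    density clustering, or no multi-cluster structure): sentences are sorted
#'    by descending token length and a prefix is taken
#'    (`strategy = "length_sort"`);
#' 4. over budget with usable topic structure: cluster exemplars, then cluster
#'    members, are taken round-robin across clusters
#'    (`strategy = "topic_round_robin"`); if the exemplars alone already
#'    exceed the cap, a greedy most-dissimilar walk over exemplars is used
#'    instead (`strategy = "topic_greedy"`).
#'
#' @param corpus Data.frame of sentence records (`rna_id`, `pmcid`,
#'   `sentence`), all for one RNA.
#' @param budget A [token_budget()].
#' @param cfg An [embedding_config()].
#' @param min_sentences Lower bound on sentence counts (default 5).
#' @param counter Token-counter backend (see [count_tokens()]).
#' @param embed_backend,reduce_backend Optional backend overrides.
#' @return A `summary_context` object.
#' @export
select_context <- function(corpus, budget = token_budget(),
                           cfg = embedding_config(), min_sentences = 5L,
                           counter = "words", embed_backend = NULL,
                           reduce_backend = NULL) {
  corpus <- prepare_corpus(corpus, counter)
  rna_id <- if (nrow(corpus) > 0) corpus$rna_id[1] else NA_character_
  empty <- corpus[0, , drop = FALSE]

  if (nrow(corpus) < min_sentences) {
    return(new_context(rna_id, empty, "skipped_too_few", counter,
                       seed = cfg$seed))
  }

  # Oversized single sentences can never be placed; drop them with a warning
  # rather than truncating (truncation would fabricate citable text).
  oversized <- corpus$token_count > budget$context_limit
  if (any(oversized)) {
    warning(sprintf("select_context: dropping %d sentence(s) longer than the %d-token cap",
                    sum(oversized), budget$context_limit), call. = FALSE)
    corpus <- corpus[!oversized, , drop = FALSE]
    rownames(corpus) <- NULL
  }

  if (sum(corpus$token_count) <= budget$context_limit) {
    return(new_context(rna_id, corpus, "all", counter, seed = cfg$seed))
  }

  clustering <- NULL
  if (nrow(corpus) >= 2 * cfg$min_cluster_size) {
    emb <- embed_sentences(corpus$sentence, cfg, backend = embed_backend)
    red <- suppressWarnings(reduce_embeddings(emb, cfg, backend = reduce_backend))
    clustering <- cluster_sentences(red, cfg)
  }
  if (is.null(clustering) || !clustering$applicable) {
    return(length_sort_fill(corpus, budget, counter = counter,
                            seed = cfg$seed))
  }

  exemplar_idx <- unlist(clustering$exemplars)
  if (sum(corpus$token_count[exemplar_idx]) > budget$context_limit) {
    return(greedy_dissimilar_fill(corpus, clustering, red, budget,
                                  counter = counter, seed = cfg$seed))
  }
  round_robin_fill(corpus, clustering, budget, counter = counter,
                   seed = cfg$seed)
}

#' Length-sorted prefix selection
#'
#' Sorts sentences by descending token length (document order breaking ties)
#' and takes the longest prefix whose cumulative token count stays within the
#' cap; selection stops at the first sentence that would overflow. If not
#' even the first sentence fits, the context is empty and flagged degenerate.
#'
#' @param corpus Sentence records with `token_count` filled (or it is filled
#'   here).
#' @inheritParams select_context
#' @param seed Seed recorded in provenance.
#' @return A `summary_context` with `strategy = "length_sort"`.
#' @export
length_sort_fill <- function(corpus, budget = token_budget(),
                             counter = "words", seed = NA_integer_) {
  corpus <- prepare_corpus(corpus, counter)
  ord <- order(-corpus$token_count, seq_len(nrow(corpus)))
  cum <- cumsum(corpus$token_count[ord])
  n_keep <- if (length(cum) == 0) 0L else {
    over <- which(cum > budget$context_limit)
    if (length(over) == 0) length(cum) else over[1] - 1L
  }
  sel <- corpus[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(sel) <- NULL
  new_context(corpus$rna_id[1], sel, "length_sort", counter,
              degenerate = n_keep == 0L, seed = seed)
}

# Build per-cluster candidate queues: exemplars first (densest first), then
# the remaining members in a seeded uniform shuffle; noise points form a
# final pseudo-cluster visited only after real clusters exhaust.
cluster_queues <- function(clustering, n, seed) {
  queues <- list()
  for (cl in seq_along(clustering$exemplars)) {
    members <- which(clustering$labels == cl - 1L)
    ex <- clustering$exemplars[[cl]]
    rest <- setdiff(members, ex)
    if (length(rest) > 1) {
      rest <- with_seed(seed + cl, sample(rest))
    }
    queues[[cl]] <- c(ex, rest)
  }
  sizes <- vapply(queues, length, integer(1))
  queues <- queues[order(-sizes, seq_along(queues))]
  noise <- which(clustering$labels == -1L)
  if (length(noise) > 1) noise <- with_seed(seed, sample(noise))
  list(queues = queues, noise = noise)
}

#' Round-robin topic selection
#'
#' Visits clusters cyclically, largest first, taking one unused sentence per
#' visit: exemplars are consumed before ordinary members, so every cluster is
#' represented before any cluster contributes twice, budget permitting.
#' Noise-labelled sentences become eligible only after every cluster is
#' exhausted. Selection stops when the next candidate would overflow the cap.
#'
#' @param corpus Sentence records.
#' @param clustering Result of [cluster_sentences()].
#' @inheritParams length_sort_fill
#' @return A `summary_context` with `strategy = "topic_round_robin"`;
#'   sentences appear in selection (cluster-interleaved) order.
#' @export
round_robin_fill <- function(corpus, clustering, budget = token_budget(),
                             counter = "words", seed = NA_integer_) {
  corpus <- prepare_corpus(corpus, counter)
  cq <- cluster_queues(clustering, nrow(corpus),
                       if (is.na(seed)) 0L else as.integer(seed))
  queues <- cq$queues
  picked <- integer()
  total <- 0L
  stopped <- FALSE
  while (!stopped && any(vapply(queues, length, integer(1)) > 0)) {
    for (ci in seq_along(queues)) {
      if (length(queues[[ci]]) == 0) next
      cand <- queues[[ci]][1]
      if (total + corpus$token_count[cand] > budget$context_limit) {
        stopped <- TRUE
        break
      }
      picked <- c(picked, cand)
      total <- total + corpus$token_count[cand]
      queues[[ci]] <- queues[[ci]][-1]
    }
  }
  if (!stopped) {
    for (cand in cq$noise) {
      if (total + corpus$token_count[cand] > budget$context_limit) break
      picked <- c(picked, cand)
      total <- total + corpus$token_count[cand]
    }
  }
  sel <- corpus[picked, , drop = FALSE]
  rownames(sel) <- NULL
  new_context(corpus$rna_id[1], sel, "topic_round_robin", counter,
              cluster_labels = clustering$labels[picked], seed = seed)
}

#' Greedy most-dissimilar exemplar selection
#'
#' Used when cluster exemplars alone exceed the token cap (very heavily
#' studied RNAs). Starts from the top exemplar of the largest cluster; at
#' each step adds the exemplar whose *maximum* cosine similarity to the
#' already-selected set is smallest (a farthest-point walk), stopping when
#' the next pick would overflow the cap. Ties break toward the lower index.
#'
#' @param corpus Sentence records.
#' @param clustering Result of [cluster_sentences()].
#' @param vectors Reduced embedding matrix aligned with `corpus` rows.
#' @inheritParams length_sort_fill
#' @return A `summary_context` with `strategy = "topic_greedy"`.
#' @export
greedy_dissimilar_fill <- function(corpus, clustering, vectors,
                                   budget = token_budget(),
                                   counter = "words", seed = NA_integer_) {
  corpus <- prepare_corpus(corpus, counter)
  sizes <- vapply(clustering$exemplars, function(e)
    sum(clustering$labels == clustering$labels[e[1]]), integer(1))
  order_clusters <- order(-sizes, seq_along(clustering$exemplars))
  candidates <- unique(unlist(clustering$exemplars[order_clusters]))
  seed_idx <- clustering$exemplars[[order_clusters[1]]][1]

  trace <- greedy_trace(vectors, candidates, seed_idx,
                        corpus$token_count, budget$context_limit)
  sel <- corpus[trace, , drop = FALSE]
  rownames(sel) <- NULL
  new_context(corpus$rna_id[1], sel, "topic_greedy", counter,
              cluster_labels = clustering$labels[trace], seed = seed)
}

# The greedy min-max-cosine walk itself, exposed for oracle comparison.
greedy_trace <- function(vectors, candidates, seed_idx, token_counts, limit) {
  seed_idx <- as.integer(seed_idx)
  candidates <- as.integer(candidates)
  if (token_counts[seed_idx] > limit) return(integer())
  selected <- seed_idx
  total <- token_counts[seed_idx]
  remaining <- setdiff(candidates, seed_idx)
  while (length(remaining) > 0) {
    worst <- vapply(remaining, function(j) {
      max(vapply(selected, function(i) cosine_sim(vectors[i, ], vectors[j, ]),
                 numeric(1)))
    }, numeric(1))
    nxt <- remaining[order(worst, remaining)][1]
    if (total + token_counts[nxt] > limit) break
    selected <- c(selected, nxt)
    total <- total + token_counts[nxt]
    remaining <- setdiff(remaining, nxt)
  }
  selected
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Serialize and restore contexts
#'
#' Contexts round-trip through JSON
#' `{rna_id, strategy, total_tokens, sentences: [{pmcid, sentence}]}` with
#' provenance fields preserved.
#'
#' @param ctx A `summary_context`.
#' @param path File path.
#' @return `read_context()` returns a `summary_context`; `write_context()`
#'   the path, invisibly.
#' @export
write_context <- function(ctx, path) {
  obj <- list(
    rna_id = ctx$rna_id,
    strategy = ctx$strategy,
    total_tokens = ctx$total_tokens,
    counter = ctx$counter,
    seed = ctx$seed,
    degenerate = ctx$degenerate,
    cluster_labels = ctx$cluster_labels,
    sentences = lapply(seq_len(nrow(ctx$sentences)), function(i) {
      list(pmcid = ctx$sentences$pmcid[i],
           sentence = ctx$sentences$sentence[i],
           token_count = ctx$sentences$token_count[i])
    })
  )
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                           null = "null")), path)
  invisible(path)
}

#' @rdname write_context
#' @export
read_context <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = ""),
                            simplifyVector = TRUE)
  sentences <- if (length(obj$sentences) == 0) {
    data.frame(rna_id = character(), pmcid = character(),
               sentence = character(), token_count = integer(),
               stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(obj$sentences, stringsAsFactors = FALSE)
    df$rna_id <- obj$rna_id
    df[, c("rna_id", "pmcid", "sentence", "token_count")]
  }
  new_context(obj$rna_id, sentences, obj$strategy, obj$counter %||% "words",
              cluster_labels = obj$cluster_labels,
              degenerate = isTRUE(obj$degenerate),
              seed = obj$seed %||% NA_integer_)
}

#' Render a context as prompt text
#'
#' One line per sentence, prefixed with the source article's PMCID so the
#' model can attribute each statement when citing.
#'
#' @param ctx A `summary_context`.
#' @return A single string.
#' @export
format_context <- function(ctx) {
  if (nrow(ctx$sentences) == 0) return("")
  paste(sprintf("[%s] %s", ctx$sentences$pmcid, ctx$sentences$sentence),
        collapse = "\n")
}
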