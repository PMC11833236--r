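#' Embedding and clustering configuration
#'
#' Parameters of the topic-selection stage: sentences are embedded into
#' `embed_dim`-dimensional vectors, reduced to `reduced_dim` dimensions, and
#' density-clustered with minimum cluster size `min_cluster_size`. Defaults
#' follow the production configuration: 384-dimensional sentence embeddings
#' reduced to 20 dimensions before clustering.
#'
#' @param embed_dim Embedding dimensionality.
#' @param reduced_dim Reduced dimensionality used for clustering.
#' @param min_cluster_size Minimum points per cluster; also the core-distance
#'   neighbourhood size of the density clusterer.
#' @param seed Integer seed for the stochastic parts of selection (member
#'   shuffles).
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(embed_dim = 384L, reduced_dim = 20L,
                             min_cluster_size = 5L, seed = 1L) {
  stopifnot(reduced_dim > 0, reduced_dim <= embed_dim, min_cluster_size >= 2)
  structure(
    list(embed_dim = as.integer(embed_dim),
         reduced_dim = as.integer(reduced_dim),
         min_cluster_size = as.integer(min_cluster_size),
         seed = as.integer(seed)),
    class = "embedding_config"
  )
}

#' Embed sentences into fixed-dimensional vectors
#'
#' The embedding backend is pluggable: any function
#' `(character vector, config) -> numeric matrix` with `embed_dim` columns may
#' be supplied (e.g. a wrapper around a pretrained sentence-transformer
#' service). The bundled default is a deterministic hashed bag-of-ngrams
#' embedding: lower-cased word unigrams and bigrams are hashed into
#' `embed_dim` signed buckets and each row is L2-normalised. It requires no
#' model download, is bitwise reproducible, and separates sentences with
#' distinct topical vocabulary, which is what the downstream clustering
#' consumes.
#'
#' @param texts Non-empty character vector.
#' @param cfg An [embedding_config()].
#' @param backend A function `(texts, cfg) -> matrix`, or `NULL` for the
#'   hashed-ngram default.
#' @return Numeric matrix, one row per text, `cfg$embed_dim` columns.
#' @export
embed_sentences <- function(texts, cfg = embedding_config(), backend = NULL) {
  if (length(texts) == 0) {
    stop("embed_sentences: empty text list", call. = FALSE)
  }
  backend <- backend %||% hashed_ngram_embedding
  mat <- backend(texts, cfg)
  stopifnot(is.matrix(mat), nrow(mat) == length(texts),
            ncol(mat) == cfg$embed_dim)
  mat
}

#' @rdname embed_sentences
#' @export
hashed_ngram_embedding <- function(texts, cfg = embedding_config()) {
  d <- cfg$embed_dim
  mat <- matrix(0, nrow = length(texts), ncol = d)
  for (i in seq_along(texts)) {
    words <- regmatches(tolower(texts[i]),
                        gregexpr("[[:alnum:]]+(?:[-'][[:alnum:]]+)*",
                                 tolower(texts[i])))[[1]]
    if (length(words) == 0) next
    feats <- words
    if (length(words) > 1) {
      feats <- c(feats, paste(head(words, -1), tail(words, -1), sep = "_"))
    }
    v <- numeric(d)
    for (f in feats) {
      idx <- (hash31(f, 31) %% d) + 1
      sgn <- if ((hash31(f, 131) %% 2) == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    mat[i, ] <- v
  }
  mat
}

#' Reduce embedding dimensionality before clustering
#'
#' Density clustering works much better in a few tens of dimensions than in
#' the raw embedding space, so embeddings are projected to `reduced_dim`
#' dimensions (20 by default) before clustering. The reduction backend is
#' pluggable; the default is principal component analysis (centred, unscaled),
#' which is deterministic for a given input. Inputs with too few rows for a
#' meaningful projection (`rows < reduced_dim + 2`) are passed through
#' unchanged with a warning.
#'
#' @param mat Numeric matrix (rows = sentences).
#' @param cfg An [embedding_config()].
#' @param backend A function `(mat, cfg) -> matrix` with `reduced_dim`
#'   columns, or `NULL` for the PCA default.
#' @return Numeric matrix with `cfg$reduced_dim` columns (or `mat` unchanged
#'   in the degenerate case).
#' @export
reduce_embeddings <- function(mat, cfg = embedding_config(), backend = NULL) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < cfg$reduced_dim + 2) {
    warning("reduce_embeddings: fewer rows than reduced_dim + 2; ",
            "passing embeddings through unreduced", call. = FALSE)
    return(mat)
  }
  backend <- backend %||% pca_reduction
  out <- backend(mat, cfg)
  stopifnot(is.matrix(out), nrow(out) == nrow(mat))
  out
}

#' @rdname reduce_embeddings
#' @export
pca_reduction <- function(mat, cfg = embedding_config()) {
  k <- cfg$reduced_dim
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  scores <- pc$x
  if (ncol(scores) < k) {
    scores <- cbind(scores, matrix(0, nrow(scores), k - ncol(scores)))
  }
  # Fix component signs so the projection is unique up to the data.
  scores <- scores[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    pivot <- which.max(abs(scores[, j]))
    if (scores[pivot, j] < 0) scores[, j] <- -scores[, j]
  }
  unname(scores)
}

#' Density-cluster reduced sentence embeddings
#'
#' Groups sentences into topics with a density-based procedure in the spirit
#' of hierarchical density clustering: each point's core distance is its
#' distance to the `min_cluster_size`-th nearest neighbour; pairwise mutual
#' reachability distances (`max(d_ij, core_i, core_j)`) feed a single-linkage
#' dendrogram; the flat cut is chosen by mean silhouette width over candidate
#' cluster counts, and components smaller than `min_cluster_size` become
#' noise (label `-1`). Clustering is declared *applicable* when at least two
#' real clusters emerge with acceptable separation; callers fall back to
#' length-sorted selection otherwise.
#'
#' Exemplars are each cluster's densest members (smallest core distance),
#' `ceiling(sqrt(cluster size))` of them, and stand in for the cluster during
#' round-robin and greedy selection.
#'
#' @param mat Numeric matrix of reduced embeddings.
#' @param cfg An [embedding_config()].
#' @param max_k Largest number of clusters considered.
#' @param min_silhouette Minimum mean silhouette width for a multi-cluster
#'   solution to be accepted.
#' @return A list with `labels` (integer vector, `-1` = noise, clusters
#'   `0..K-1`), `exemplars` (list of integer index vectors, one per cluster,
#'   densest first), `k` (number of clusters), and `applicable` (logical,
#'   `k >= 2`).
#' @export
cluster_sentences <- function(mat, cfg = embedding_config(), max_k = 10L,
                              min_silhouette = 0.25) {
  n <- nrow(mat)
  inapplicable <- list(labels = rep(-1L, n), exemplars = list(), k = 0L,
                       applicable = FALSE)
  if (n < 2 * cfg$min_cluster_size) {
    return(inapplicable)
  }
  d <- as.matrix(stats::dist(mat))
  k_core <- min(cfg$min_cluster_size, n - 1L)
  core <- apply(d, 1, function(row) sort(row)[k_core + 1L])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")

  best <- list(score = -Inf, labels = NULL, k = 0L)
  for (k_try in 2:min(max_k, n - 1L)) {
    cut <- stats::cutree(hc, k = k_try)
    sizes <- table(cut)
    real <- as.integer(names(sizes)[sizes >= cfg$min_cluster_size])
    if (length(real) < 2) next
    labels <- ifelse(cut %in% real, match(cut, real) - 1L, -1L)
    score <- mean_silhouette(d, labels)
    if (is.finite(score) && score > best$score) {
      best <- list(score = score, labels = as.integer(labels),
                   k = length(real))
    }
  }
  if (best$k < 2 || best$score < min_silhouette) {
    return(inapplicable)
  }
  labels <- best$labels
  exemplars <- lapply(seq_len(best$k) - 1L, function(cl) {
    members <- which(labels == cl)
    m <- max(1L, ceiling(sqrt(length(members))))
    members[order(core[members], members)][seq_len(min(m, length(members)))]
  })
  list(labels = labels, exemplars = exemplars, k = best$k, applicable = TRUE)
}

# Mean silhouette width over non-noise points, from a distance matrix.
mean_silhouette <- function(d, labels) {
  keep <- which(labels >= 0)
  labs <- labels[keep]
  uniq <- unique(labs)
  if (length(uniq) < 2) return(NA_real_)
  s <- numeric(length(keep))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    own <- keep[labs == labs[ii]]
    own <- setdiff(own, i)
    a <- if (length(own) == 0) 0 else mean(d[i, own])
    b <- Inf
    for (cl in setdiff(uniq, labs[ii])) {
      other <- keep[labs == cl]
      b <- min(b, mean(d[i, other]))
    }
    s[ii] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
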