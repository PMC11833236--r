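test_that("selection dispatches each corpus to exactly one strategy", {
  strategies <- c("all", "length_sort", "topic_round_robin", "topic_greedy",
                  "skipped_too_few")
  # below the sentence floor
  small <- head(make_corpus(corpus_spec(n_articles = 2, seed = 2)), 4)
  ctx <- select_context(small)
  expect_identical(ctx$strategy, "skipped_too_few")
  expect_equal(nrow(ctx$sentences), 0)
  # exactly at the floor, fitting the budget
  five <- head(make_corpus(corpus_spec(n_articles = 2, seed = 3)), 5)
  ctx <- select_context(five)
  expect_identical(ctx$strategy, "all")
  expect_equal(nrow(ctx$sentences), 5)
  # over budget, too few sentences for clustering
  lng <- head(make_corpus(corpus_spec(n_articles = 3, n_topics = 1,
                                      token_length_range = c(300, 400),
                                      seed = 4)), 8)
  expect_identical(select_context(lng)$strategy, "length_sort")
  # over budget with topic structure
  big <- make_corpus(corpus_spec(n_articles = 30, sentences_per_article = 6,
                                 n_topics = 4, token_length_range = c(20, 40),
                                 seed = 5))
  ctx <- select_context(big)
  expect_identical(ctx$strategy, "topic_round_robin")
  expect_lte(ctx$total_tokens, token_budget()$context_limit)
  # exemplars alone over budget
  huge <- make_corpus(corpus_spec(n_articles = 60, sentences_per_article = 8,
                                  n_topics = 4,
                                  token_length_range = c(150, 200), seed = 6))
  ctx <- select_context(huge)
  expect_identical(ctx$strategy, "topic_greedy")
  expect_lte(ctx$total_tokens, token_budget()$context_limit)
  expect_true(ctx$strategy %in% strategies)
})

test_that("mixed-id corpora are rejected", {
  corp <- make_corpus(corpus_spec(n_articles = 3, seed = 1))
  corp$rna_id[1] <- "other-id"
  expect_error(select_context(corp), "mixes rna_ids")
})

test_that("length-sorted fill takes the longest prefix under the cap", {
  corp <- data.frame(
    rna_id = "x", pmcid = paste0("PMC", 1:4),
    sentence = c("a", "b", "c", "d"),
    token_count = c(500L, 400L, 300L, 200L), stringsAsFactors = FALSE)
  ctx <- length_sort_fill(corp, token_budget(context_limit = 1000))
  expect_identical(ctx$sentences$pmcid, c("PMC1", "PMC2"))
  expect_equal(ctx$total_tokens, 900L)
  # nothing fits: degenerate empty context
  ctx <- length_sort_fill(corp[1, ], token_budget(context_limit = 100))
  expect_equal(nrow(ctx$sentences), 0)
  expect_true(ctx$degenerate)
  # ties keep document order
  corp$token_count <- rep(100L, 4)
  ctx <- length_sort_fill(corp, token_budget(context_limit = 250))
  expect_identical(ctx$sentences$pmcid, c("PMC1", "PMC2"))
})

test_that("round-robin fill covers every cluster before any repeats", {
  corp <- data.frame(
    rna_id = "x", pmcid = paste0("PMC", 1:3),
    sentence = c("a1", "a2", "b1"), token_count = rep(1L, 3),
    stringsAsFactors = FALSE)
  clustering <- list(labels = c(0L, 0L, 1L), exemplars = list(1L, 3L),
                     k = 2L, applicable = TRUE)
  ctx <- round_robin_fill(corp, clustering, token_budget(context_limit = 3),
                          seed = 1)
  expect_identical(ctx$sentences$sentence, c("a1", "b1", "a2"))
  # budget for exactly one per cluster
  ctx <- round_robin_fill(corp, clustering, token_budget(context_limit = 2),
                          seed = 1)
  expect_identical(sort(ctx$sentences$sentence), c("a1", "b1"))
  # zero budget
  ctx <- round_robin_fill(corp, clustering,
                          token_budget(model_window = 4096, context_limit = 1,
                                       slack = 4000), seed = 1)
  expect_lte(nrow(ctx$sentences), 1)
})

test_that("greedy selection matches the brute-force min-max-cosine trace", {
  vecs <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1))
  trace <- rnasumm:::greedy_trace(vecs, candidates = 1:3, seed_idx = 1,
                                  token_counts = rep(1L, 3), limit = 10)
  expect_identical(trace[2], 3L)  # least similar to (1,0) is (0,1)
  expect_identical(trace, oracle_greedy_trace(vecs, 1:3, 1L, rep(1L, 3), 10))

  # single exemplar
  expect_identical(
    rnasumm:::greedy_trace(vecs[1, , drop = FALSE], 1, 1, 5L, 10), 1L)

  # all greedy traces for n <= 8 random exemplar sets match the oracle
  for (seed in 1:20) {
    n <- 3 + (seed %% 6)
    vecs <- matrix(with_seed_test(seed, stats::rnorm(n * 5)), nrow = n)
    tokens <- rep(1L, n)
    trace <- rnasumm:::greedy_trace(vecs, seq_len(n), 1L, tokens, n)
    expect_identical(trace, oracle_greedy_trace(vecs, seq_len(n), 1L, tokens, n))
  }
})

test_that("budget safety, subset, and mention invariants hold across regimes", {
  limit <- token_budget()$context_limit
  for (seed in 1:8) {
    corp <- make_corpus(corpus_spec(n_articles = 20 + seed * 3,
                                    sentences_per_article = 6, n_topics = 4,
                                    token_length_range = c(20, 45),
                                    seed = seed))
    ctx <- select_context(corp)
    if (ctx$strategy != "skipped_too_few") {
      recount <- sum(vapply(ctx$sentences$sentence, count_tokens, integer(1)))
      expect_lte(recount, limit)
    }
    key <- paste(ctx$sentences$pmcid, ctx$sentences$sentence)
    expect_true(all(key %in% paste(corp$pmcid, corp$sentence)))
    expect_false(anyDuplicated(key) > 0)
    expect_true(all(grepl("hsa-mir-21", ctx$sentences$sentence, fixed = TRUE)))
  }
})

test_that("identical corpus, seed, and config reproduce identical contexts", {
  corp <- make_corpus(corpus_spec(n_articles = 30, sentences_per_article = 6,
                                  n_topics = 4, seed = 9))
  c1 <- select_context(corp, cfg = embedding_config(seed = 5))
  c2 <- select_context(corp, cfg = embedding_config(seed = 5))
  expect_identical(c1, c2)
})

test_that("oversized single sentences are dropped with a warning, not truncated", {
  corp <- make_corpus(corpus_spec(n_articles = 3, seed = 10))
  corp$sentence[1] <- paste(c("hsa-mir-21", rep("filler", 3000)), collapse = " ")
  expect_warning(ctx <- select_context(corp), "dropping")
  expect_false(corp$sentence[1] %in% ctx$sentences$sentence)
})

test_that("contexts round-trip through JSON", {
  ctx <- make_test_context(seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_context(ctx, path)
  back <- read_context(path)
  expect_identical(back$rna_id, ctx$rna_id)
  expect_identical(back$strategy, ctx$strategy)
  expect_identical(back$sentences$sentence, ctx$sentences$sentence)
  expect_equal(back$total_tokens, ctx$total_tokens)
})
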