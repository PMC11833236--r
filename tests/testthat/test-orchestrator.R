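generation_templates <- c("initial", "rescue_adequacy", "rescue_identifier",
                          "rescue_placement", "rescue_concentration")

count_generation_calls <- function(backend) {
  sum(vapply(backend_log(backend),
             function(e) e$template_name %in% generation_templates,
             logical(1)))
}

test_that("each scripted pipeline path lands on its designated status", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 11))
  cfg <- pipeline_config(seed = 5)
  for (path in c("first_pass_clean", "rescue_then_clean", "exhaust_four",
                 "consistency_revise")) {
    sc <- make_script(path, select_context(corp), seed = 5)
    be <- scripted_backend(sc$queue)
    res <- run_one("hsa-mir-21", corp, be, cfg)
    expect_identical(res$status, sc$expected_status, info = path)
    expect_identical(res$ref_status, sc$expected_ref_status, info = path)
    expect_identical(res$consistency_status, sc$expected_consistency_status,
                     info = path)
    expect_equal(count_generation_calls(be), sc$expected_generation_calls,
                 info = path)
  }
})

test_that("a sub-floor corpus short-circuits without any model call", {
  small <- head(make_corpus(corpus_spec(n_articles = 2, seed = 12)), 4)
  be <- scripted_backend(list(initial = "should never be used"))
  res <- run_one("hsa-mir-21", small, be, pipeline_config())
  expect_identical(res$status, "skipped_too_few")
  expect_false(res$displayable)
  expect_length(backend_log(be), 0)
})

test_that("the rescue loop records which rescue produced each attempt", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 13))
  sc <- make_script("rescue_then_clean", select_context(corp), seed = 2)
  be <- scripted_backend(sc$queue)
  res <- run_one("hsa-mir-21", corp, be, pipeline_config())
  expect_length(res$attempts, 2)
  expect_true(is.na(res$attempts[[1]]$rescue_used))
  expect_identical(res$attempts[[2]]$rescue_used, "rescue_adequacy")
  expect_false(res$attempts[[1]]$passed)
  expect_true(res$attempts[[2]]$passed)
})

test_that("attempt cap bounds generation calls and flags exhaustion", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 14))
  sc <- make_script("exhaust_four", select_context(corp), seed = 3)
  be <- scripted_backend(sc$queue)
  res <- run_one("hsa-mir-21", corp, be, pipeline_config(max_attempts = 4))
  expect_identical(res$status, "flagged_refs_exhausted")
  expect_equal(count_generation_calls(be), 4)
  expect_length(res$attempts, 4)
  expect_false(res$displayable)
  # the consistency stage never ran
  expect_false(any(vapply(backend_log(be),
                          function(e) e$template_name == "consistency_check",
                          logical(1))))
})

test_that("transport exhaustion yields a flagged result, not a crash", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 15))
  be <- scripted_backend(list())  # empty queue: first call is a transport error
  res <- run_one("hsa-mir-21", corp, be, pipeline_config())
  expect_identical(res$status, "flagged_transport")
  expect_match(res$error_detail, "queue exhausted")
  expect_false(res$displayable)
})

test_that("batch statistics equal hand-computed fractions over known statuses", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 16))
  ctx <- select_context(corp)
  paths <- c("first_pass_clean", "rescue_then_clean", "exhaust_four",
             "consistency_revise", "first_pass_clean")
  results <- lapply(seq_along(paths), function(i) {
    sc <- make_script(paths[i], ctx, seed = i)
    run_one(paste0("rna-", i), corp, scripted_backend(sc$queue),
            pipeline_config())
  })
  # append one skipped item
  small <- head(make_corpus(corpus_spec(n_articles = 2, seed = 17)), 3)
  results <- c(results, list(
    run_one("rna-skip", small, scripted_backend(list()), pipeline_config())))

  st <- batch_stats(results)
  expect_equal(st$n_total, 6)
  expect_equal(st$n_skipped, 1)
  expect_equal(st$n_attempted, 5)
  expect_equal(st$rates$refs_first_pass, 3 / 5)
  expect_equal(st$rates$refs_after_revision, 4 / 5)
  expect_equal(st$rates$consistency_no_problems, 3 / 4)
  expect_equal(st$rates$consistency_after_revision, 4 / 4)
  expect_equal(st$n_displayable, 4)
  expect_equal(nrow(st$table), 4)

  # empty batch: no division by zero
  st0 <- batch_stats(list())
  expect_equal(st0$n_total, 0)
  expect_true(is.na(st0$rates$refs_first_pass))
})

test_that("batch replay is deterministic and isolates per-item failures", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 18))
  ctx <- select_context(corp)
  make_run <- function() {
    sc1 <- make_script("first_pass_clean", ctx, seed = 1)
    sc2 <- make_script("consistency_revise", ctx, seed = 2)
    be <- scripted_backend(list(
      initial = c(sc1$queue$initial, sc2$queue$initial),
      consistency_check = c(sc1$queue$consistency_check,
                            sc2$queue$consistency_check),
      consistency_revise = sc2$queue$consistency_revise))
    run_batch(c("rna-a", "rna-b"), list(corp, corp), be,
              pipeline_config(seed = 7))
  }
  b1 <- make_run(); b2 <- make_run()
  expect_identical(b1, b2)
  expect_identical(vapply(b1$results, function(r) r$rna_id, character(1)),
                   c("rna-a", "rna-b"))
})

test_that("flagged results never surface in the displayable export", {
  corp <- make_corpus(corpus_spec(n_articles = 5, sentences_per_article = 3,
                                  n_topics = 2, seed = 19))
  ctx <- select_context(corp)
  sc_ok <- make_script("first_pass_clean", ctx, seed = 1)
  sc_bad <- make_script("exhaust_four", ctx, seed = 2)
  results <- list(
    run_one("rna-ok", corp, scripted_backend(sc_ok$queue), pipeline_config()),
    run_one("rna-bad", corp, scripted_backend(sc_bad$queue), pipeline_config()))
  path <- withr::local_tempfile(fileext = ".jsonl")
  recs <- export_results(results, path)
  expect_length(recs, 1)
  expect_identical(recs[[1]]$rna_id, "rna-ok")
  expect_gt(length(recs[[1]]$pmcids_cited), 0)
  on_disk <- read_jsonl(path)
  expect_length(on_disk, 1)
  # flagged summary text is retained on the result object itself
  expect_false(is.null(results[[2]]$final_summary))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_stats_csv(batch_stats(results), csv)
  tab <- utils::read.csv(csv)
  expect_identical(tab$failure_mode[1], "References - first pass")
})
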