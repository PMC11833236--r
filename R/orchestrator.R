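#' Pipeline configuration
#'
#' Bundles every tunable of a summarization run: the attempt cap (at most
#' four generation attempts per RNA), check thresholds, token budget,
#' initial-call sampling parameters, embedding configuration, the seed, and
#' the display policy (flagged summaries are retained but, under
#' `"hide_flagged"`, excluded from the displayable export).
#'
#' @param max_attempts Maximum total generation attempts (initial + rescues).
#' @param thresholds A [check_thresholds()].
#' @param budget A [token_budget()].
#' @param params A [generation_params()] for the initial call.
#' @param cfg An [embedding_config()].
#' @param min_sentences Sentence-count floor for summarization.
#' @param seed Integer seed.
#' @param display_policy `"hide_flagged"` or `"show_all"`.
#' @param counter Token-counter backend.
#' @param model_name Model label recorded in run metadata.
#' @param template_dir Optional template directory override.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_attempts = 4L,
                            thresholds = check_thresholds(),
                            budget = token_budget(),
                            params = generation_params(),
                            cfg = embedding_config(),
                            min_sentences = 5L,
                            seed = 1L,
                            display_policy = c("hide_flagged", "show_all"),
                            counter = "words",
                            model_name = "scripted",
                            template_dir = NULL) {
  stopifnot(max_attempts >= 1)
  structure(
    list(max_attempts = as.integer(max_attempts), thresholds = thresholds,
         budget = budget, params = params, cfg = cfg,
         min_sentences = as.integer(min_sentences),
         seed = as.integer(seed),
         display_policy = match.arg(display_policy), counter = counter,
         model_name = model_name, template_dir = template_dir),
    class = "pipeline_config"
  )
}

new_pipeline_result <- function(rna_id, final_summary, ref_status,
                                consistency_status, attempts,
                                consistency_report, context, config,
                                error_detail = NULL) {
  flagged <- (!is.na(ref_status) &&
                ref_status %in% c("flagged_refs_exhausted", "flagged_transport")) ||
    (!is.na(consistency_status) && consistency_status == "flagged_consistency")
  skipped <- !is.na(ref_status) && ref_status == "skipped_too_few"
  displayable <- if (config$display_policy == "hide_flagged") {
    !flagged && !skipped && !is.null(final_summary)
  } else {
    !skipped && !is.null(final_summary)
  }
  status <- if (!is.na(consistency_status)) consistency_status else ref_status
  structure(
    list(rna_id = rna_id,
         final_summary = final_summary,
         status = status,
         ref_status = ref_status,
         consistency_status = consistency_status,
         attempts = attempts,
         consistency_report = consistency_report,
         displayable = displayable,
         strategy = if (is.null(context)) NA_character_ else context$strategy,
         context = context,
         error_detail = error_detail,
         metadata = list(model = config$model_name,
                         seed = config$seed,
                         selection_strategy = if (is.null(context))
                           NA_character_ else context$strategy,
                         config_hash = config_hash(
                           config[c("max_attempts", "min_sentences",
                                    "display_policy", "counter")]))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: status=%s (refs=%s, consistency=%s), %d attempt(s)\n",
              x$rna_id, x$status, x$ref_status,
              x$consistency_status %||% NA, length(x$attempts)))
  invisible(x)
}

#' Run the full summarization pipeline for one RNA
#'
#' The per-RNA pipeline: select a token-budgeted context (early return with
#' status `skipped_too_few` below the sentence floor); generate a summary;
#' run the five reference checks, applying the first failing check's rescue
#' prompt and regenerating, up to `max_attempts` total generation attempts
#' (exhaustion flags the result and skips the consistency stage); then one
#' bullet-wise self-consistency pass with at most one revision; a revised
#' summary receives a final reference check. The result carries a
#' reference-stage status (`refs_first_pass`, `refs_after_revision`,
#' `flagged_refs_exhausted`, `skipped_too_few`) and, when reached, a
#' consistency-stage status (`consistency_clean`, `consistency_revised`,
#' `flagged_consistency`), plus the full attempt history and exchange log.
#'
#' @param rna_id RNA identifier string.
#' @param corpus Sentence records for this RNA.
#' @param backend An LLM backend.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`.
#' @export
run_one <- function(rna_id, corpus, backend, config = pipeline_config()) {
  ctx <- select_context(corpus, budget = config$budget, cfg = config$cfg,
                        min_sentences = config$min_sentences,
                        counter = config$counter)
  if (ctx$strategy == "skipped_too_few") {
    return(new_pipeline_result(rna_id, NULL, "skipped_too_few",
                               NA_character_, list(), NULL, ctx, config))
  }

  attempts <- list()
  summary <- NULL
  audit <- NULL
  rescue <- NULL

  run_generation <- function(template_name, bindings, params) {
    prompt <- render_prompt(load_template(template_name,
                                          dir = config$template_dir),
                            bindings)
    llm_complete(backend, template_name, prompt, params,
                 budget = config$budget, counter = config$counter)
  }

  result <- tryCatch({
    for (attempt in seq_len(config$max_attempts)) {
      if (attempt == 1) {
        summary <- run_generation(
          "initial",
          list(rna_id = rna_id, context = format_context(ctx)),
          config$params)
      } else {
        summary <- run_generation(
          rescue,
          list(rna_id = rna_id, context = format_context(ctx),
               summary = summary),
          conservative_params(config$params$max_output_tokens))
      }
      audit <- run_reference_checks(summary, ctx, config$thresholds)
      attempts[[attempt]] <- list(
        attempt_index = attempt,
        summary_text = summary,
        check_reports = audit$reports,
        passed = audit$passed,
        rescue_used = if (attempt == 1) NA_character_ else rescue)
      if (audit$passed) break
      rescue <- audit$rescue_template
    }

    if (!audit$passed) {
      return(new_pipeline_result(rna_id, summary, "flagged_refs_exhausted",
                                 NA_character_, attempts, NULL, ctx, config))
    }
    ref_status <- if (length(attempts) == 1) "refs_first_pass" else
      "refs_after_revision"

    cp <- consistency_pass(summary, ctx, backend,
                           params = conservative_params(
                             config$params$max_output_tokens),
                           budget = config$budget, counter = config$counter,
                           template_dir = config$template_dir)
    if (!cp$revised) {
      return(new_pipeline_result(rna_id, summary, ref_status,
                                 "consistency_clean", attempts, cp$report,
                                 ctx, config))
    }
    final_audit <- run_reference_checks(cp$summary, ctx, config$thresholds)
    if (final_audit$passed) {
      new_pipeline_result(rna_id, cp$summary, ref_status,
                          "consistency_revised", attempts, cp$report, ctx,
                          config)
    } else {
      new_pipeline_result(rna_id, cp$summary, ref_status,
                          "flagged_consistency", attempts, cp$report, ctx,
                          config)
    }
  }, transport_error = function(e) {
    new_pipeline_result(rna_id, summary, "flagged_transport", NA_character_,
                        attempts, NULL, ctx, config,
                        error_detail = conditionMessage(e))
  })
  result
}

#' Run the pipeline over a batch of RNAs
#'
#' Sequential execution with per-item isolation: one RNA's failure never
#' aborts the batch, and results come back in input order regardless of
#' anything else, so exports are reproducible.
#'
#' @param ids Character vector of RNA ids.
#' @param corpora Named list (by id) or positional list of sentence-record
#'   data.frames.
#' @param backend An LLM backend.
#' @param config A [pipeline_config()].
#' @return A list with `results` (list of `pipeline_result`) and `stats`
#'   (see [batch_stats()]).
#' @export
run_batch <- function(ids, corpora, backend, config = pipeline_config()) {
  results <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    corpus <- if (!is.null(names(corpora))) corpora[[ids[i]]] else corpora[[i]]
    results[[i]] <- tryCatch(
      run_one(ids[i], corpus, backend, config),
      error = function(e) {
        new_pipeline_result(ids[i], NULL, "flagged_transport", NA_character_,
                            list(), NULL, NULL, config,
                            error_detail = conditionMessage(e))
      })
  }
  list(results = results, stats = batch_stats(results))
}

#' Batch pass-rate statistics
#'
#' Cumulative pass rates per stage, mirroring the production report format:
#' the reference stage's first-pass and after-revision rates (over all
#' non-skipped items), and the consistency stage's no-problem and
#' after-revision rates (over items that reached the consistency stage).
#' Also reports mean generation attempts and total token usage cannot be
#' computed here (tokens are logged per backend); rates are `NA` when a
#' denominator is zero.
#'
#' @param results List of `pipeline_result` objects.
#' @return A list with counts, the four rates (fractions in `[0, 1]`),
#'   `mean_attempts`, and `table` (a data.frame with one labelled row per
#'   rate).
#' @export
batch_stats <- function(results) {
  ref <- vapply(results, function(r) r$ref_status, character(1))
  con <- vapply(results, function(r) r$consistency_status %||% NA_character_,
                character(1))
  n_total <- length(results)
  n_skipped <- sum(ref == "skipped_too_few", na.rm = TRUE)
  n_attempted <- n_total - n_skipped
  n_first <- sum(ref == "refs_first_pass", na.rm = TRUE)
  n_after <- sum(ref == "refs_after_revision", na.rm = TRUE)
  n_entered <- sum(!is.na(con))
  n_clean <- sum(con == "consistency_clean", na.rm = TRUE)
  n_revised <- sum(con == "consistency_revised", na.rm = TRUE)

  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  rates <- list(
    refs_first_pass = rate(n_first, n_attempted),
    refs_after_revision = rate(n_first + n_after, n_attempted),
    consistency_no_problems = rate(n_clean, n_entered),
    consistency_after_revision = rate(n_clean + n_revised, n_entered)
  )
  attempts <- vapply(results, function(r) length(r$attempts), integer(1))
  tab <- data.frame(
    failure_mode = c("References - first pass",
                     "References - after revision",
                     "Self-consistency - no problems found",
                     "Self-consistency - no problems after revision"),
    pass_rate_pct = round(100 * unlist(rates), 1),
    n_passing = c(n_first, n_first + n_after, n_clean, n_clean + n_revised),
    stringsAsFactors = FALSE
  )
  list(n_total = n_total, n_skipped = n_skipped, n_attempted = n_attempted,
       n_entered_consistency = n_entered,
       n_displayable = sum(vapply(results, function(r) isTRUE(r$displayable),
                                  logical(1))),
       rates = rates,
       mean_attempts = if (n_attempted == 0) NA_real_ else
         mean(attempts[ref != "skipped_too_few"]),
       table = tab)
}

#' Export displayable summaries
#'
#' JSONL export `{rna_id, summary, pmcids_cited, status, metadata}`; under
#' the default policy only displayable results (not flagged, not skipped)
#' are written — flagged summaries are retained in the result objects but
#' never surface here.
#'
#' @param results List of `pipeline_result` objects.
#' @param path Output path.
#' @param displayable_only Export only displayable results (default `TRUE`).
#' @return The exported records, invisibly.
#' @export
export_results <- function(results, path, displayable_only = TRUE) {
  keep <- if (displayable_only) {
    Filter(function(r) isTRUE(r$displayable), results)
  } else {
    Filter(function(r) !is.null(r$final_summary), results)
  }
  recs <- lapply(keep, function(r) {
    cited <- unique(unlist(parse_citations(r$final_summary)$pmcids))
    list(rna_id = r$rna_id, summary = r$final_summary,
         pmcids_cited = as.list(cited %||% character()),
         status = r$status, metadata = r$metadata)
  })
  write_jsonl(recs, path)
  invisible(recs)
}

#' Write batch statistics as CSV
#'
#' @param stats Result of [batch_stats()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats$table, path, row.names = FALSE)
  invisible(path)
}
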