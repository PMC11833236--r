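#' Synthetic corpus specification
#'
#' Defines a deterministic, template-based sentence corpus emulating
#' harvested literature: every sentence mentions the RNA id verbatim, is
#' tagged with a PMC-style article id unique within the corpus, and belongs
#' to one of up to four topical templates (expression, disease association,
#' localization, interaction) with controlled per-topic vocabulary so
#' embedding-based clustering can recover the planted structure. Defaults
#' describe a moderately studied RNA: 10 articles of about 5 sentences each,
#' sentences of 15-40 words.
#'
#' @param rna_id RNA identifier placed verbatim in every sentence.
#' @param n_articles Number of articles.
#' @param sentences_per_article Mean sentences per article (Poisson, min 1).
#' @param n_topics Number of distinct topics (1-4).
#' @param token_length_range Target sentence length range, in words.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(rna_id = "hsa-mir-21", n_articles = 10L,
                        sentences_per_article = 5,
                        n_topics = 4L, token_length_range = c(15L, 40L),
                        seed = 1L) {
  stopifnot(n_topics >= 1, n_topics <= 4, n_articles >= 1,
            length(token_length_range) == 2,
            token_length_range[1] <= token_length_range[2])
  structure(
    list(rna_id = rna_id, n_articles = as.integer(n_articles),
         sentences_per_article = sentences_per_article,
         n_topics = as.integer(n_topics),
         token_length_range = as.integer(token_length_range),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

topic_vocabularies <- function() {
  list(
    expression = list(
      verbs = c("was upregulated", "was markedly elevated",
                "showed increased expression", "was strongly induced",
                "was downregulated"),
      nouns = c("transcript levels", "expression levels", "qPCR signal",
                "northern blot intensity", "read counts"),
      places = c("in tumour tissue", "in liver samples", "in plasma",
                 "in biopsy specimens", "in cultured fibroblasts"),
      filler = c("according to quantitative profiling",
                 "across replicate expression assays",
                 "relative to matched control tissue",
                 "in the transcriptomic screen",
                 "under serum starvation conditions")),
    disease = list(
      verbs = c("was associated with", "predicted", "correlated with",
                "served as a biomarker for", "stratified"),
      nouns = c("poor prognosis", "overall survival", "tumour stage",
                "metastatic spread", "therapy resistance"),
      places = c("in gastric carcinoma patients", "in a melanoma cohort",
                 "in colorectal cancer", "in chronic heart failure",
                 "in diabetic nephropathy"),
      filler = c("in a multivariate clinical model",
                 "among the enrolled patient cohort",
                 "after adjusting for age and stage",
                 "in the retrospective case series",
                 "with significant hazard ratios")),
    localization = list(
      verbs = c("localized to", "accumulated in", "was enriched in",
                "was retained in", "shuttled between"),
      nouns = c("the nucleus", "nuclear speckles", "the cytoplasm",
                "stress granules", "the chromatin fraction"),
      places = c("during interphase", "upon heat shock",
                 "in differentiated neurons", "after serum stimulation",
                 "in fractionation assays"),
      filler = c("as shown by in situ hybridization",
                 "according to imaging of fixed cells",
                 "in subcellular fractionation experiments",
                 "consistent with compartment markers",
                 "under confocal microscopy")),
    interaction = list(
      verbs = c("directly bound", "interacted with", "sequestered",
                "formed a complex with", "sponged"),
      nouns = c("the EZH2 protein", "HuR", "miR-134", "the PRC2 complex",
                "STAT3 transcripts"),
      places = c("in pulldown assays", "in crosslinking experiments",
                 "in reporter assays", "in immunoprecipitates",
                 "in the RNA interactome screen"),
      filler = c("supporting a scaffolding function",
                 "suggesting competitive binding",
                 "with nanomolar affinity",
                 "as confirmed by mutagenesis",
                 "through conserved sequence motifs"))
  )
}

make_topic_sentence <- function(rna_id, topic, target_words) {
  v <- topic_vocabularies()[[topic]]
  base <- sprintf("%s %s %s %s", rna_id, sample(v$verbs, 1),
                  sample(v$nouns, 1), sample(v$places, 1))
  while (length(strsplit(base, "\\s+")[[1]]) < target_words) {
    base <- paste0(base, ", ", sample(v$filler, 1))
  }
  paste0(base, ".")
}

#' Generate a synthetic sentence corpus
#'
#' Deterministic in the spec's seed. Topics are assigned cyclically so they
#' stay balanced; article PMCIDs are drawn from the `PMC1xxxxx` range, which
#' is disjoint from the `PMC9xxxxxx` range used for invented identifiers, so
#' realness violations are always unambiguous.
#'
#' @param spec A [corpus_spec()].
#' @return A data.frame of sentence records (`rna_id`, `pmcid`, `sentence`,
#'   `topic`).
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  topics <- names(topic_vocabularies())[seq_len(spec$n_topics)]
  with_seed(spec$seed, {
    n_per_article <- pmax(1L, stats::rpois(spec$n_articles,
                                           spec$sentences_per_article))
    total <- sum(n_per_article)
    if (spec$n_topics > total) {
      stop("corpus_spec error: n_topics exceeds total sentence count",
           call. = FALSE)
    }
    rows <- vector("list", total)
    k <- 0L
    for (a in seq_len(spec$n_articles)) {
      pmcid <- sprintf("PMC1%05d", (spec$seed %% 400) * 100 + a)
      for (s in seq_len(n_per_article[a])) {
        k <- k + 1L
        topic <- topics[((k - 1L) %% length(topics)) + 1L]
        target <- sample(seq(spec$token_length_range[1],
                             spec$token_length_range[2]), 1)
        rows[[k]] <- data.frame(
          rna_id = spec$rna_id, pmcid = pmcid,
          sentence = make_topic_sentence(spec$rna_id, topic, target),
          topic = topic, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out[!duplicated(out[, c("pmcid", "sentence")]), , drop = FALSE]
  })
}

#' Defective-summary specification
#'
#' Names one of the pipeline's archetypal failure modes. Each defect
#' violates exactly one of the five reference checks against its base
#' context, except `unsupported_claim`, which passes all five and is only
#' detectable by the consistency stage (the "unsupported expansion"
#' archetype).
#'
#' @param defect One of `none`, `too_few_refs`, `non_pmc_format`,
#'   `invented_pmcid`, `trailing_ref_block`, `stacked_refs`,
#'   `unsupported_claim`.
#' @param base_context A non-empty `summary_context`.
#' @param seed Integer seed.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(defect, base_context, seed = 1L) {
  defect <- match.arg(defect, c("none", "too_few_refs", "non_pmc_format",
                                "invented_pmcid", "trailing_ref_block",
                                "stacked_refs", "unsupported_claim"))
  if (nrow(base_context$sentences) == 0) {
    stop("defect_spec: base_context is empty", call. = FALSE)
  }
  structure(list(defect = defect, base_context = base_context,
                 seed = as.integer(seed)),
            class = "defect_spec")
}

clean_summary_from <- function(context, seed, n_sentences = 4L) {
  pmcids <- unique(context$sentences$pmcid)
  claims <- c("has been linked to malignant progression",
              "shows tissue-specific expression",
              "accumulates in distinct subcellular compartments",
              "participates in regulatory protein complexes",
              "has been profiled across patient cohorts",
              "modulates downstream signalling output")
  with_seed(seed, {
    picked <- sample(claims, n_sentences, replace = n_sentences > length(claims))
    cite <- pmcids[((seq_len(n_sentences) - 1L) %% length(pmcids)) + 1L]
    paste(sprintf("The RNA %s %s [%s].", context$rna_id, picked, cite),
          collapse = " ")
  })
}

#' Generate a summary failing exactly one named check
#'
#' Builds a clean, fully referenced summary from the base context and then
#' injects the named defect. Before returning, the result is verified
#' against [run_reference_checks()]: the intended check (and only it) must
#' fail, or the generator stops — defect orthogonality is the module's core
#' guarantee.
#'
#' @param spec A [defect_spec()].
#' @param thresholds A [check_thresholds()].
#' @return A summary string.
#' @export
make_defective_summary <- function(spec, thresholds = check_thresholds()) {
  stopifnot(inherits(spec, "defect_spec"))
  ctx <- spec$base_context
  pmcids <- unique(ctx$sentences$pmcid)
  need <- c(none = 1L, too_few_refs = 1L, non_pmc_format = 1L,
            invented_pmcid = 2L, trailing_ref_block = 2L, stacked_refs = 4L,
            unsupported_claim = 1L)[[spec$defect]]
  if (length(pmcids) < need) {
    stop("defect_spec error: defect '", spec$defect, "' needs at least ",
         need, " distinct context pmcids", call. = FALSE)
  }

  summary <- switch(
    spec$defect,
    none = clean_summary_from(ctx, spec$seed),
    too_few_refs = {
      base <- clean_summary_from(ctx, spec$seed, n_sentences = 5L)
      # Keep one citation out of five: ratio 0.2 < 0.5; one ref total is
      # exempt from concentration and terminal, so only adequacy fails.
      parts <- segment_sentences(base)
      stripped <- gsub(" \\[PMC[0-9]+\\]", "", parts[-1])
      paste(c(parts[1], stripped), collapse = " ")
    },
    non_pmc_format = {
      base <- clean_summary_from(ctx, spec$seed)
      paste(base, "Earlier reviews reached similar conclusions [1].")
    },
    invented_pmcid = {
      base <- clean_summary_from(ctx, spec$seed)
      fake <- sprintf("PMC9%06d", (spec$seed %% 899999) + 100000)
      sub("\\[PMC[0-9]+\\]", paste0("[", fake, "]"), base)
    },
    trailing_ref_block = {
      base <- clean_summary_from(ctx, spec$seed, n_sentences = 4L)
      cited <- regmatches(base, gregexpr("PMC[0-9]+", base))[[1]]
      stripped <- gsub(" \\[PMC[0-9]+\\]", "", base)
      paste0(stripped, " ",
             paste(sprintf("[%s]", unique(cited)), collapse = " "))
    },
    stacked_refs = {
      with_seed(spec$seed, {
        ids <- sample(pmcids, 4)
        sprintf(paste0("The RNA %s has been studied extensively [%s]. ",
                       "Converging evidence supports its clinical relevance ",
                       "[%s, %s, %s]."),
                ctx$rna_id, ids[1], ids[2], ids[3], ids[4])
      })
    },
    unsupported_claim = {
      base <- clean_summary_from(ctx, spec$seed, n_sentences = 3L)
      extra <- sprintf(
        "The RNA %s also resolves DFU, expanded as diabetic foot ulcer, in affected patients [%s].",
        ctx$rna_id, pmcids[1])
      paste(base, extra)
    })

  audit <- run_reference_checks(summary, ctx, thresholds)
  failed <- names(audit$reports)[!vapply(audit$reports, function(r) r$passed,
                                         logical(1))]
  expected <- switch(spec$defect,
                     none = character(), unsupported_claim = character(),
                     too_few_refs = "adequacy", non_pmc_format = "formatting",
                     invented_pmcid = "realness",
                     trailing_ref_block = "placement",
                     stacked_refs = "concentration")
  if (!identical(sort(failed), sort(expected))) {
    stop("make_defective_summary: defect '", spec$defect,
         "' produced checks {", paste(failed, collapse = ","),
         "} instead of {", paste(expected, collapse = ","), "}",
         call. = FALSE)
  }
  summary
}

#' Scripted transcripts for named pipeline paths
#'
#' Builds a [scripted_backend()] queue realizing one named end-to-end path,
#' together with the status the path must produce:
#'
#' * `first_pass_clean` — one clean generation, all-TRUE verdicts;
#' * `rescue_then_clean` — an under-referenced first attempt, a clean rescue,
#'   all-TRUE verdicts;
#' * `exhaust_four` — four under-referenced attempts (attempt cap reached);
#' * `consistency_revise` — one clean generation, one FALSE verdict, one
#'   clean revision.
#'
#' @param path Path name.
#' @param context A `summary_context` the scripted summaries cite.
#' @param seed Integer seed.
#' @return A list with `queue` (for [scripted_backend()]), `expected_status`,
#'   `expected_ref_status`, `expected_consistency_status`, and
#'   `expected_generation_calls`.
#' @export
make_script <- function(path, context, seed = 1L) {
  path <- match.arg(path, c("first_pass_clean", "rescue_then_clean",
                            "exhaust_four", "consistency_revise"))
  clean <- clean_summary_from(context, seed)
  bad <- make_defective_summary(defect_spec("too_few_refs", context, seed))
  verdict_lines <- function(summary, false_at = integer()) {
    bullets <- split_bullets(summary)
    paste(vapply(seq_along(bullets), function(i) {
      if (i %in% false_at) {
        sprintf("%d. FALSE - the context does not support this statement.", i)
      } else {
        sprintf("%d. TRUE - supported by the cited context sentence.", i)
      }
    }, character(1)), collapse = "\n")
  }
  switch(
    path,
    first_pass_clean = list(
      queue = list(initial = clean,
                   consistency_check = verdict_lines(clean)),
      expected_status = "consistency_clean",
      expected_ref_status = "refs_first_pass",
      expected_consistency_status = "consistency_clean",
      expected_generation_calls = 1L),
    rescue_then_clean = list(
      queue = list(initial = bad,
                   rescue_adequacy = clean,
                   consistency_check = verdict_lines(clean)),
      expected_status = "consistency_clean",
      expected_ref_status = "refs_after_revision",
      expected_consistency_status = "consistency_clean",
      expected_generation_calls = 2L),
    exhaust_four = list(
      queue = list(initial = bad,
                   rescue_adequacy = rep(bad, 3)),
      expected_status = "flagged_refs_exhausted",
      expected_ref_status = "flagged_refs_exhausted",
      expected_consistency_status = NA_character_,
      expected_generation_calls = 4L),
    consistency_revise = {
      revised <- clean_summary_from(context, seed + 1000L)
      list(
        queue = list(initial = clean,
                     consistency_check = verdict_lines(clean, false_at = 2L),
                     consistency_revise = revised),
        expected_status = "consistency_revised",
        expected_ref_status = "refs_first_pass",
        expected_consistency_status = "consistency_revised",
        expected_generation_calls = 1L)
    })
}
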