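# Shared fixture builders for the suite.

# A small fits-within-budget context (strategy "all") with at least
# `min_pmcids` distinct articles.
make_test_context <- function(seed = 1, n_articles = 5, n_topics = 2) {
  corp <- make_corpus(corpus_spec(n_articles = n_articles,
                                  sentences_per_article = 3,
                                  n_topics = n_topics, seed = seed))
  select_context(corp)
}

with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

all_defects <- c("none", "too_few_refs", "non_pmc_format", "invented_pmcid",
                 "trailing_ref_block", "stacked_refs", "unsupported_claim")

defect_to_check <- c(too_few_refs = "adequacy", non_pmc_format = "formatting",
                     invented_pmcid = "realness",
                     trailing_ref_block = "placement",
                     stacked_refs = "concentration")
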