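Package: rnasumm
Title: Referenced Literature Summaries for Noncoding RNAs via Audited LLM Prompt Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds token-budgeted literature contexts from per-RNA sentence
    corpora and drives a large language model through a chain of summary
    generation, citation-provenance checks, rescue prompts, and bullet-wise
    self-consistency verification, emitting referenced summaries with full
    per-stage provenance. Includes local sentence harvesting from article
    full text, embedding-based topic selection of sentences under a token
    budget, five automated reference checks with check-specific rescue
    prompts, a deterministic scripted LLM backend for offline testing, and a
    synthetic fixture generator covering every selection regime and pipeline
    path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    curl
Config/testthat/edition: 3
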