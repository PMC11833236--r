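# rnasumm

Referenced literature summaries for noncoding RNAs via audited LLM prompt
chains.

## The problem

Noncoding RNA knowledgebases index hundreds of thousands of transcripts,
but almost none have a curated prose overview of their literature — there
are vastly more RNAs than curator hours. Large language models can draft
such overviews, but an LLM summary is only usable for curation if every
statement traces to a source article and every failure of that
traceability is caught mechanically: LLMs invent facts, invent
identifiers, and misplace citations.

`rnasumm` implements the full pipeline: harvest identifier-mentioning
sentences from article full text; assemble a token-budgeted context;
generate a summary through an LLM with controlled sampling parameters;
audit its citations with five deterministic checks, each paired with a
check-specific rescue prompt (at most four generation attempts per RNA);
fact-check the surviving summary bullet by bullet against its context with
one revision round; and emit results with full per-stage provenance.
Everything runs offline against a deterministic scripted backend, so the
whole chain is testable without network or model downloads; a real
chat-completion endpoint plugs in behind the same interface.

## The method in brief

**Context construction.** Sentence corpora are capped at 2560 tokens of a
4096-token model window (the remainder covers the prompt, the ~255-token
summary, and a ~1150-token revision round; tokens ≈ words / 0.75). Corpora
with fewer than five sentences are skipped; corpora that fit are used
whole; oversized corpora are selected either by descending token length
(no topic structure) or by topic: sentences are embedded (384-d), reduced
to 20 dimensions, density-clustered, and cluster exemplars then members
are drawn round-robin across clusters — or, when exemplars alone exceed
the cap, by a greedy farthest-point walk minimizing the maximum cosine
similarity to the already-selected set.

**Reference audit.** Five checks on parsed citation instances, in order:
adequacy (≥ 0.5 references per sentence), formatting (bracketed
`PMC<digits>` only), realness (every cited id occurs in the context),
placement (citations at sentence ends, no trailing reference block),
concentration (no instance holds > 50% of all references). The first
failing check selects the rescue prompt for regeneration.

**Self-consistency.** The summary is split into bullets; the model returns
`TRUE`/`FALSE` verdicts with explanations per bullet, judged only against
the context; any failure (including unparseable verdicts — the check
fails closed) triggers exactly one revision, followed by a final reference
check.

## Worked example

A complete run on a synthetic corpus with the scripted backend, driving
the consistency-revision path:

```r
library(rnasumm)

corpus <- make_corpus(corpus_spec(rna_id = "hsa-mir-21", n_articles = 5,
                                  sentences_per_article = 3, n_topics = 2,
                                  seed = 11))
ctx <- select_context(corpus)
ctx
#> <summary_context> hsa-mir-21: 8 sentences, 329 tokens, strategy=all

sc <- make_script("consistency_revise", ctx, seed = 5)
backend <- scripted_backend(sc$queue)
res <- run_one("hsa-mir-21", corpus, backend, pipeline_config(seed = 5))
res
#> <pipeline_result> hsa-mir-21: status=consistency_revised (refs=refs_first_pass,
#>   consistency=consistency_revised), 1 attempt(s)

cat(res$final_summary)
#> The RNA hsa-mir-21 shows tissue-specific expression [PMC101101]. The RNA
#> hsa-mir-21 has been linked to malignant progression [PMC101102]. The RNA
#> hsa-mir-21 modulates downstream signalling output [PMC101103]. The RNA
#> hsa-mir-21 has been profiled across patient cohorts [PMC101104].

batch_stats(list(res))$table
#>                                                   failure_mode pass_rate_pct n_passing
#>                                        References - first pass           100         1
#>                                    References - after revision           100         1
#>                           Self-consistency - no problems found             0         0
#>                  Self-consistency - no problems after revision           100         1
```

The 8-sentence corpus fits the 2560-token cap, so no selection is applied
(`strategy=all`). The scripted transcript delivers a clean first summary
(reference checks pass first time), one `FALSE` bullet verdict (so the
consistency stage revises once), and a revision that passes the final
reference check — hence `consistency_revised`, with every cited PMCID
present in the context.

A thin CLI over the same functions is included:

```sh
Rscript inst/cli/rnasumm.R harvest --articles articles/ --id hsa-mir-21 --out sentences.jsonl
Rscript inst/cli/rnasumm.R context --in sentences.jsonl --out context.json
Rscript inst/cli/rnasumm.R audit   --summary summary.txt --context context.json
```

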