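---
title: "Audited literature summaries for noncoding RNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audited literature summaries for noncoding RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasumm)
```

## The problem

Literature curation cannot keep pace with publication. For noncoding RNAs in
particular, tens of thousands of transcripts have at least some primary
literature, but almost none have a curated prose overview. `rnasumm`
implements a pipeline that turns per-RNA collections of literature sentences
into short, referenced summaries using a large language model (LLM), and —
because LLMs invent facts and identifiers — wraps every generation call in a
chain of deterministic citation audits, rescue prompts, and a bullet-wise
self-consistency check. The package's premise is that an LLM summary is only
usable for curation if every statement can be traced to a source article and
every failure of that traceability is detected mechanically.

The pipeline has five stages, each an independently testable module:

1. **harvest** — extract sentences mentioning an RNA id from article full
   text (a local emulation of literature-index sentence mining);
2. **context building** — assemble a token-budgeted context from the
   sentence corpus, selecting for topical coverage when the corpus is too
   large;
3. **prompting** — render templates and call an LLM backend with controlled
   sampling parameters;
4. **reference audit** — five deterministic checks on the citations in the
   generated summary, each paired with a rescue prompt;
5. **consistency** — LLM-mediated bullet-by-bullet fact-checking against
   the context, with one revision round.

An orchestrator drives the stages per RNA and aggregates batch statistics;
a fixture module generates synthetic corpora, defect-bearing summaries, and
scripted LLM transcripts so that the whole pipeline runs and is tested
offline, with no model downloads and no network.

## Sentence harvesting

The query template couples the quoted RNA id with six RNA-type terms
(`"rna"`, `"mrna"`, `"ncrna"`, `"lncrna"`, `"rrna"`, `"sncrna"`) and
restricts to open-access, full-text-indexed, non-preprint records; this is
reproduced verbatim by `build_query()` because the term list is what keeps
serial identifiers from drowning in false positives.

Mention matching is case-insensitive with word boundaries defined as any
character that is neither alphanumeric nor a hyphen (or a string edge).
The hyphen rule matters: identifiers like `hsa-mir-21` must not match
inside `hsa-mir-210`, and id substrings are the dominant false-positive
mode for serial identifiers. Aliases (cross-reference names) contribute
sentences under the primary id, and each record stores which surface form
matched.

Sentence segmentation is rule-based: a boundary is a run of `.`, `!`, `?`
followed by whitespace and an uppercase letter or digit, with a guard list
of abbreviations (`Fig.`, `et al.`, `e.g.`, ...), and blank lines always
terminate a sentence. The segmenter is deliberately conservative (it will
merge a sentence that begins with a lowercase identifier into its
predecessor rather than risk splitting inside an abbreviation), and it is
the *single* sentence-counting convention used everywhere in the package —
extraction, adequacy ratios, citation placement, and bullet decomposition
all agree by construction. The segmenter is a plain function, so a
statistical segmenter can be substituted where higher fidelity matters.

Network retrieval is behind a transport interface; the package ships only
the local transport (`read_articles()`) serving `<PMCID>.txt` files or
JSONL records. Live index traffic is out of scope by design.

## Token accounting and the context budget

All budget decisions use `count_tokens()`. Two deterministic backends are
provided: the default follows the standard rule of thumb of one token per
0.75 English words (`ceiling(words / 0.75)`); an alternative subword
heuristic counts punctuation as single tokens and fragments words into
8-character chunks, approximating how byte-pair-encoding vocabularies
fragment English prose. The two agree within ±40% on generated prose
fixtures, which the suite asserts; any function `text -> integer` (e.g. a
wrapper around a model-exact tokenizer) can be supplied instead.

The default `token_budget()` partitions a 4096-token model window: 2560
tokens of literature context (~1920 words), ~255 tokens of generated
summary, up to 140 tokens of prompt text, and ~1150 tokens reserved for the
revision round (consumed in a separate call, hence the documented slack).
The 2560 cap is enforced twice: at selection time, and by recounting the
emitted context in the tests.

## Sentence selection

`select_context()` dispatches among four regimes:

* fewer than five sentences — nothing is summarized
  (`skipped_too_few`). Five is a floor, not a sample: five sentences from a
  single paper are enough to summarize the only source about an RNA, and
  below it a "summary" would be a paraphrase.
* the whole corpus fits in 2560 tokens — no selection (`all`); this is the
  common case.
* over budget, but no usable topic structure — sentences are sorted by
  descending token length and the longest prefix under the cap is taken
  (`length_sort`). Longer sentences are preferred on the grounds that they
  carry more of the corpus's information per selection slot.
* over budget with topic structure — sentences are embedded, reduced, and
  density-clustered; cluster exemplars, then remaining members, are taken
  round-robin across clusters (`topic_round_robin`). When the exemplars
  alone exceed the cap (very heavily studied RNAs), a greedy
  most-dissimilar walk over exemplars is used instead (`topic_greedy`).

"Usable topic structure" had to be made precise: clustering is considered
applicable iff the corpus has at least `2 * min_cluster_size` sentences
(default 10) *and* the clusterer finds at least two real clusters;
otherwise selection falls back to `length_sort`. Density clustering below
that floor is meaningless.

Other decisions in this stage, each recorded in the context's provenance:

* Round-robin visits clusters in descending size order (ties toward the
  lower label), consistent with the greedy walk starting at the largest
  cluster. Every cluster contributes one sentence before any contributes
  two, budget permitting; selection stops at the first candidate that
  would overflow.
* Within a cluster, exemplars are consumed densest-first; the remaining
  members follow in a seeded uniform shuffle (sampling implies randomness;
  the seed makes it reproducible).
* Noise-labelled sentences become eligible only after every cluster
  exhausts — topical coverage first.
* The greedy walk minimizes the *maximum* cosine similarity (on the
  reduced vectors) between a candidate and the already-selected set — the
  standard farthest-point heuristic; ties break toward the lower index, so
  the trace is deterministic and equals an exhaustive search of the same
  criterion (asserted for n ≤ 8).
* A single sentence longer than the whole cap is dropped with a warning,
  never truncated: truncation would fabricate text the LLM could cite.
* The emitted context preserves selection order (cluster-interleaved), not
  document order; the order is part of provenance either way.

## Embedding, reduction, clustering

The embedding backend is pluggable. The bundled default is a hashed
bag-of-ngrams embedding into 384 signed buckets (matching the
dimensionality of the small pretrained sentence-transformer commonly used
for this task, so a transformer backend can be swapped in without
reconfiguring anything downstream). Lower-cased word unigrams and bigrams
are hashed with a deterministic 31-bit polynomial hash; rows are
L2-normalised. This embedding is bitwise reproducible, needs no model
download, and separates sentences with distinct topical vocabulary — which
is precisely the signal the clustering stage consumes. What it does *not*
capture is synonymy or word order beyond bigrams; passing tests with this
backend demonstrates the selection machinery, not state-of-the-art
semantic similarity.

Embeddings are reduced to 20 dimensions before clustering — density
clustering performs much better in a few tens of dimensions. The reduction
backend is pluggable; the default is principal component analysis
(centred, unscaled, component signs fixed by the largest-magnitude
loading), which is deterministic for a given input. Inputs with fewer than
`reduced_dim + 2` rows pass through unchanged with a warning.

`cluster_sentences()` is a hierarchical density clusterer built from
standard primitives: each point's core distance is its distance to the
`min_cluster_size`-th nearest neighbour; pairwise mutual-reachability
distances (`max(d_ij, core_i, core_j)`) feed a single-linkage dendrogram;
candidate flat cuts at k = 2..10 are filtered (clusters smaller than
`min_cluster_size` become noise, label −1) and scored by mean silhouette
width on the original distances; the best cut wins if its silhouette
exceeds 0.25, otherwise the corpus is declared unclusterable. Exemplars
are each cluster's densest members — smallest core distance,
`ceiling(sqrt(size))` of them. The numbers here (silhouette threshold
0.25, cut range up to 10, the exemplar count rule) are the package's own
choices: the threshold rejects solutions whose between-cluster separation
is comparable to within-cluster spread, and the square-root exemplar rule
keeps exemplar token mass sublinear in cluster size.

## Prompting

Seven templates drive the pipeline: `initial`, four rescue templates,
`consistency_check`, and `consistency_revise`. They live as editable text
files under `inst/templates/` with a front-matter line naming their
placeholders; rendering is literal `{name}` substitution with no escaping
and no re-scanning (context text containing braces cannot trigger further
substitution). The initial template instructs the model to use only the
provided context, to cite every sentence with PubMed-Central-style
identifiers (`PMC` + digits) in square brackets at sentence ends, with an
example, and not to stack many identifiers in one bracket.

Five checks share four rescue templates: the formatting and realness
checks both concern identifier validity and share `rescue_identifier`.
Which checks share a template is an assumption — the constraint adopted is
four rescue prompts for five checks, and identifier validity is the
natural seam.

The initial generation call uses temperature 0.1, presence penalty −2,
and frequency penalty 1: low temperature for near-deterministic output,
the strongly negative presence penalty to encourage restating tokens from
the context (a summary *should* reuse its source vocabulary), and the
positive frequency penalty to avoid degenerate repetition. Rescue,
consistency, and revision calls use neutral penalties at the same
temperature — checking and revising should be conservative; this split is
a package decision.

Every call goes through `llm_complete()`, which enforces the token-window
guard *before* any network activity and appends one exchange record
(template name, rendered prompt, parameters, response, token usage) to the
backend log — the audit trail is complete by construction. The scripted
backend replays queued responses keyed by template name and is exactly
reproducible; the HTTP backend serializes an OpenAI-style chat payload
(`build_chat_request()` is exposed so parameter fidelity is testable
without network) and retries transport failures a bounded number of times.

## The five reference checks

`run_reference_checks()` parses citation instances (bracketed PMCID
groups and bare PMC tokens, with character spans, sentence indices, and
terminality) and runs, in fixed order:

1. **adequacy** — at least 0.5 references per sentence. References are
   counted with multiplicity (a two-id instance contributes two): the
   ratio is "references per sentence", and nothing in its intent suggests
   de-duplication.
2. **formatting** — every citation-like token must be a well-formed
   bracketed PMCID group. Numeric markers (`[1]`), `PMID`/`doi` tokens,
   malformed ids (`[PMCabc]`), and — in the default strict mode —
   parenthesized groups `(PMC1)` all fail; a lenient mode accepts the
   parenthesized dialect.
3. **realness** — every cited PMCID must occur in the context; this
   catches invented identifiers. An uncited summary passes vacuously
   (adequacy owns absence).
4. **placement** — citations belong at sentence ends. Two failure modes:
   *all* instances trailing the prose behind a sentence terminator (the
   classic all-references-dumped-at-the-end summary), or more than 20% of
   instances sitting mid-sentence. The 0.2 tolerance operationalizes
   "usually at the end of sentences" and is configurable. A terminal
   citation on the final sentence is *not* trailing — the distinguishing
   feature is a sentence terminator between the last prose character and
   the citation block.
5. **concentration** — no instance may hold more than half of all
   references. Below three total references the check passes vacuously:
   a literal 50% rule would reject every single-citation summary, which
   cannot be the intent of an anti-dumping rule.

The first failing check selects the rescue prompt. The order
(adequacy, formatting, realness, placement, concentration) runs from the
cheapest-to-diagnose failure to the most stylistic; no ordering is
inherent in the checks themselves.

Every check is pure and is verified against an independent brute-force
re-implementation (regex scan and set arithmetic, sharing no code with the
package) on over a thousand seeded defect fixtures, with the
defect-to-detected-check confusion matrix required to be exactly diagonal.

## Consistency checking

The summary is split into bullets (one per segmented sentence, citations
retained) and the model is asked for a per-bullet TRUE/FALSE verdict *with
an explanation* — asking for the reason, not just the verdict, is what
makes the check usable as revision input. The response grammar
(`<index>. TRUE|FALSE - <explanation>`) is imposed by the template and
parsed tolerantly: case-insensitive verdicts, flexible separators. Any
line that cannot be parsed — including a verdict with an empty
explanation — becomes `UNPARSEABLE`, which counts as a failure. The
fail-closed rule is central: a verdict the pipeline cannot read must
trigger revision, never silently pass.

If any bullet fails, exactly one revision call feeds back the summary, the
flagged verdict lines, and the context. One round, not iteration until
clean: residual inconsistency after a single feedback round is an
acknowledged property of this procedure, and iterating multiplies cost
while inviting oscillation. The module never edits summary text itself —
all edits come from the backend, so provenance stays pure. After a
revision, the orchestrator re-runs the *reference* checks only (a final
check), not the consistency check again.

Known limitation: "feedback hallucination" — a hallucinated instruction in
the check output that the revision then obediently inserts — is not
detected. Neither are wrong inferences with indirect support in the
context; the check judges each bullet against the context as the model
reads it.

## Orchestration and statuses

Per RNA: select a context (early return when skipped); generate; audit;
on failure, apply the first failing check's rescue prompt and regenerate,
up to **four total generation attempts** (the cap counts the initial
attempt plus up to three rescues — the literal reading of "four attempts
to produce a summary"); exhaustion flags the result and skips the
consistency stage. Results carry a reference-stage status
(`refs_first_pass`, `refs_after_revision`, `flagged_refs_exhausted`,
`skipped_too_few`) and, when reached, a consistency-stage status
(`consistency_clean`, `consistency_revised`, `flagged_consistency`), plus
the full attempt history, check reports, and exchange log. Transport
exhaustion yields `flagged_transport` with detail — never a crash
mid-batch. The attempt counter is global per item; it does not reset when
the failing check changes between attempts.

Flagged summaries are retained in the result objects but excluded from
the displayable export under the default `hide_flagged` policy.

Batches run sequentially with per-item error isolation, in input order.
Sequential execution (rather than a worker pool) is a deliberate choice:
byte-identical replay under the scripted backend is a package invariant,
and per-item work at desk scale is sub-second, so concurrency buys
nothing that determinism doesn't pay for. `batch_stats()` reports
cumulative pass rates per stage — reference first-pass and
after-revision rates over non-skipped items, consistency no-problem and
after-revision rates over items that entered the consistency stage — with
`NA` (never division by zero) on empty denominators.

## The synthetic fixture generator

`make_corpus()` emulates harvested literature: every sentence contains the
RNA id verbatim, carries a PMC-style article id unique within the corpus,
and is built from one of four topical templates (expression, disease
association, localization, interaction) with controlled per-topic
vocabulary. Topics are assigned cyclically so they stay balanced, sentence
lengths are drawn from a configurable range (default 15–40 words, a
realistic span for literature sentences), and article sentence counts are
Poisson around a configurable mean. Real article ids live in the
`PMC1xxxxx` range and invented ids in `PMC9xxxxxx`, so realness violations
are unambiguous by construction.

What the generator does *not* emulate: real scientific prose (synonymy,
anaphora, hedging), unbalanced topic distributions, near-duplicate
sentences from citation chains, or noisy sentence segmentation in the
source. Consequently, passing selection tests demonstrates the budget,
coverage, and determinism machinery — not that topic clustering of real
literature recovers scientifically meaningful themes.

`make_defective_summary()` produces a summary failing *exactly* one named
check (verified internally before returning), one defect per check, plus
`unsupported_claim`, which passes all five reference checks and is
detectable only by the consistency stage. `make_script()` assembles
scripted-backend queues realizing four named pipeline paths
(`first_pass_clean`, `rescue_then_clean`, `exhaust_four`,
`consistency_revise`) together with the status each must produce.

## Numerical choices and degenerate inputs

* Ties in length sorting break toward document order; ties in the greedy
  walk toward the lower index; cluster-visit ties toward the lower label.
  Every tie-break is deterministic, which is what makes byte-identical
  replay possible.
* Empty corpus, empty summary, zero-sentence adequacy input, empty batch:
  each has a defined behavior (skip, input error, input error, NA-rates)
  asserted in the suite.
* The RNG is touched only through a save/restore wrapper seeded from
  configuration, so library calls never disturb a caller's RNG state.
* All hashes are 31-bit polynomial hashes computed in doubles (exact below
  2^53), so embeddings and config hashes are identical across platforms.

## Problem sizes in the test suite

The suite runs entirely offline with the deterministic backends: defect
fixtures (7 defects × 143 seeds × rotating contexts, >1000 fixtures)
checked against the independent oracle; 200 seeded corpora spanning all
four selection regimes for budget/coverage/determinism properties; 50
seeds of 4-topic corpora (~125 sentences each) for planted-topic
recovery, with a ≥90% recovery requirement; and 25 randomized greedy
traces against exhaustive search. These sizes were chosen to exercise
every regime boundary while keeping the default run in the low minutes on
one core.

## Known limitations

* The hashed embedding is a lexical device; swap in a transformer backend
  for semantic similarity on real corpora.
* The consistency check inherits every blind spot of LLM self-checking:
  indirect support, over-inference, feedback hallucination.
* Reference *misattribution* — a real, in-context PMCID attached to the
  wrong claim — passes all five reference checks by design; only the
  consistency stage (or a human) can catch it.
* Organism disambiguation for non-species-specific identifiers is out of
  scope; the pipeline summarizes whatever corpus it is handed.
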