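placeholders: rna_id, context, summary
---
In the summary below of the noncoding RNA "{rna_id}", too many references
are concentrated in a single citation. No single pair of brackets may hold
more than half of all the references in the summary.

Rewrite the summary so that each sentence cites the article(s) that support
it, spreading the PubMed Central identifiers (formatted like PMC1234567, in
square brackets at sentence ends) across the sentences they belong to. Use
only identifiers and facts from the context; do not use external sources.

Context:
{context}

Summary to fix:
{summary}

Rewritten summary:
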