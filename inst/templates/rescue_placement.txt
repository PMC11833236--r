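placeholders: rna_id, context, summary
---
In the summary below of the noncoding RNA "{rna_id}", the references are not
placed where they belong: references must appear at the end of the sentence
they support, not collected in a block at the end of the summary or dropped
mid-sentence.

Rewrite the summary so every sentence ends with the PubMed Central
identifier(s) of the article(s) supporting it, formatted like PMC1234567 in
square brackets. Use only identifiers and facts from the context; do not use
external sources.

Context:
{context}

Summary to fix:
{summary}

Rewritten summary:
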