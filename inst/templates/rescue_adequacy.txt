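placeholders: rna_id, context, summary
---
The summary below of the noncoding RNA "{rna_id}" does not contain enough
references for its length. Rewrite it so that, on the whole, there is at
least one reference for every two sentences, ideally one per sentence.

Cite only PubMed Central identifiers that appear in the context, formatted
like PMC1234567 in square brackets at the end of the sentence each supports.
Use only facts from the context; do not use external sources.

Context:
{context}

Summary to fix:
{summary}

Rewritten summary:
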