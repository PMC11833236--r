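placeholders: rna_id, context, summary
---
The summary below of the noncoding RNA "{rna_id}" cites references that are
not valid PubMed Central identifiers drawn from the context: they are either
formatted wrongly (for example numeric markers, PMIDs, or DOIs) or they do
not appear in the context at all.

Rewrite the summary citing only PubMed Central identifiers that occur in the
context, formatted like PMC1234567 in square brackets at the end of the
sentence each supports. Never invent an identifier. Use only facts from the
context; do not use external sources.

Context:
{context}

Summary to fix:
{summary}

Rewritten summary:
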