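placeholders: rna_id, context
---
You are an experienced biomedical curator. Write a short literature summary
for the noncoding RNA "{rna_id}".

Use ONLY the statements in the context below. Do not use external sources or
any knowledge that is not present in the context; if the context does not
support a statement, leave it out.

Cite the supporting article for every sentence using PubMed Central
identifiers, formatted like PMC1234567, in square brackets at the end of the
sentence it supports. For example: "{rna_id} is upregulated in gastric
cancer tissue [PMC1234567]." Use references throughout the summary, citing
each statement with the identifier of the article it came from, and do not
collect many identifiers into one pair of brackets.

Context:
{context}

Summary of {rna_id}:
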