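placeholders: summary, issues, context
---
The summary below contains statements that are not supported by the context
it was generated from. The fact-check verdicts listing the problems are
given after the summary.

Amend the summary: remove or correct every statement flagged as false or
unsupported, and keep all accurate statements and their references intact.
Cite PubMed Central identifiers from the context, formatted like PMC1234567
in square brackets at the end of each sentence. Use only facts from the
context; do not use external sources.

Summary:
{summary}

Problems found:
{issues}

Context:
{context}

Amended summary:
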