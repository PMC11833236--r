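placeholders: bullets, context
---
Below is a summary of a noncoding RNA, broken into numbered bullet points,
followed by the context it was generated from.

For each bullet, state whether it is true or false based ONLY on the
context. Give an explanation for every verdict, quoting the supporting
passage from the context where possible. Judge only against the context; do
not use outside knowledge.

Answer with exactly one line per bullet, in this form:
1. TRUE - <explanation with supporting quote>
2. FALSE - <explanation of what the context fails to support>

Bullets:
{bullets}

Context:
{context}

Verdicts:
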