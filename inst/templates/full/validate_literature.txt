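Decide whether the research question below has already been studied in the
literature, using only the candidate records listed. Cite the ids of records
that genuinely address the same question; cite nothing if none do.

Question: {question}

Candidate records:
{records}

Reply with a JSON object {"record_ids": [...]}.
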