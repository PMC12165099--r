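You are a biomedical researcher generating scientific questions directly from
a structured dataset. Propose up to {n_candidates} specific, testable research
questions that can be answered with the variables below. Each question must
name at least one variable exactly as listed, state the population implicitly
as this cohort, and be answerable by statistical analysis of the table alone.

{data_report}

Reply with a JSON array of question strings.
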