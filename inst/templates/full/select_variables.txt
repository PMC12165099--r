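Select the variables needed to answer the question below from the profiled
dataset: the primary variables (outcome and exposure named or implied by the
question) and potential confounders that should be adjusted for.

Question: {question}

{data_report}

Reply with a JSON object {"primary": [...], "confounders": [...],
"rationale": ...} using exact variable names.
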