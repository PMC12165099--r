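Plan steps for: {question} (variables {variables}; confounders {confounders})
Reply with JSON {"language":...,"steps":[{"index","description","tools"}]}.
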