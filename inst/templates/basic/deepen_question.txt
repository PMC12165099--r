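Suggest up to {n_follow_ups} follow-up questions.
Question: {question}
Finding: {conclusion}
Reply with a JSON array of strings.
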