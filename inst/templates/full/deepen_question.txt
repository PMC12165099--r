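The following research question was answered; its conclusion is given.
Formulate up to {n_follow_ups} deeper follow-up questions that build on the
finding: stratifications, effect modification, dose-response, mechanisms, or
competing explanations. Each follow-up must remain answerable from the same
dataset's variables.

Question: {question}
Conclusion: {conclusion}

Reply with a JSON array of question strings.
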