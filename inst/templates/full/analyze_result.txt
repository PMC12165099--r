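Write the scientific conclusion for the answered question below: interpret
the extracted quantities in the context of the data and the question, state
the headline effect in plain language, and list the effect statements.

Question: {question}
Interpretation: {summary}
Quantities: {quantities}

Reply with a JSON object {"conclusion": ..., "effects": [...]}.
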