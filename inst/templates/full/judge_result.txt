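Judge whether the analysis output adequately answers the research question.
Assess three dimensions strictly: question - the output addresses the
specific question under investigation, not a related one; variable -
confounding factors were appropriately considered (selection below);
process - the methodology and logic were correctly followed. Explain each
verdict and give detailed feedback usable by a code debugger.

Question: {question}
Interpretation: {summary}
Extracted quantities: {quantities}
Output tail: {stdout_tail}
Primary variables: {variables}
Confounders: {confounders}

Reply with a JSON object {"question": "pass"/"fail", "variable":
"pass"/"fail", "process": "pass"/"fail", "question_reason": ...,
"variable_reason": ..., "process_reason": ..., "feedback": ...,
"confidence": number in [0,1]}.
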