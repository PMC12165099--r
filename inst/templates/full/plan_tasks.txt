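Break the analysis of the question below into an ordered sequence of concrete
steps (chain of thought): think through what must happen first, what depends
on what, and which software tool each step needs. Keep steps atomic and
executable.

Question: {question}
Primary variables: {variables}
Confounders to adjust for: {confounders}

Reply with a JSON object {"language": ..., "steps": [{"index": 1,
"description": ..., "tools": [...]}, ...]}.
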