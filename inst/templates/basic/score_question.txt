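Score 1-100 per rubric criterion.
Question: {question}
{rubric}
Reply with JSON {"difficulty":{...},"quality":{...}}.
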