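Score the research question below on every criterion of the rubric, each on
a 1-100 integer scale (higher is better for quality criteria; higher means
harder for difficulty criteria).

Question: {question}

Rubric:
{rubric}

Reply with a JSON object {"difficulty": {criterion: score, ...},
"quality": {criterion: score, ...}} covering every criterion.
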