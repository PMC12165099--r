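You are a scientific reviewer. For each candidate research question below,
decide whether it has genuine research value: retain questions that are
specific, testable against the data, and of potential scientific
significance; reject vague, trivial or unanswerable ones.

{questions}

Reply with a JSON array of objects
{"question_id": ..., "retained": true/false, "reason": ...},
exactly one per candidate.
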