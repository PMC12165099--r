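You are assisting an autonomous analysis of a structured biomedical table.
Classify each profiled variable into the analytic roles it can plausibly
play, using prior biomedical knowledge. Valid relations: {relations}.
A variable may appear under several roles.

Variable profiles:
{profile_summary}

Reply with a JSON array of objects {"subject": ..., "relation": ..., "rationale": ...}.
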