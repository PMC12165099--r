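The script below failed; the judge's feedback explains how. Produce the
corrected code fragment that fixes the fault (only the part that must
change).

Script:
{source}

Feedback:
{feedback}

Reply with a JSON object {"fragment": ...}.
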