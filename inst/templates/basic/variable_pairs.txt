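Classify these variables by role ({relations}).
{profile_summary}
Reply with a JSON array of {"subject","relation","rationale"} objects.
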