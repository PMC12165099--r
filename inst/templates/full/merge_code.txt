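Integrate the corrected fragment into the original script to produce a
complete, runnable replacement. Preserve everything that was correct; the
result must be the whole script, not a diff.

Original:
{source}

Corrected fragment:
{fragment}

Reply with a JSON object {"source": ...}.
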