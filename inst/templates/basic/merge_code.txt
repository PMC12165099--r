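Merge fragment into script; reply whole script as JSON {"source":...}.
{source}
---
{fragment}
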