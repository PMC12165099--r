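Conclude for: {question}
{summary} ({quantities})
Reply with JSON {"conclusion":...,"effects":[...]}.
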