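Depth of domain knowledge required to pose and interpret the question.
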