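The question can realistically be answered with the available data and standard methods.
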