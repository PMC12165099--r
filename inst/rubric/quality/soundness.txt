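The question rests on sound biomedical reasoning and a plausible mechanism.
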