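Which datasets fit {question}?
{catalog}
Reply with JSON {"dataset_ids":[...]}.
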