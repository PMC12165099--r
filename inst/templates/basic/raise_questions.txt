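Propose up to {n_candidates} research questions about this dataset.
{data_report}
Reply with a JSON array of strings.
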