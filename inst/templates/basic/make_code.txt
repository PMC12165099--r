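Write a {language} script for:
{steps}
(dataset {dataset_id}; variables {variables}; confounders {confounders})
Reply with JSON {"language":...,"source":...}.
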