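Write a complete, runnable {language} script implementing the plan below.
The script must run non-interactively, print its key quantitative results to
stdout as "name: value" lines, and exit nonzero on failure.

Plan:
{steps}

Dataset: {dataset_id}
Primary variables: {variables}
Confounders: {confounders}

Reply with a JSON object {"language": ..., "source": ...}.
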