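From the catalog below, list the ids of datasets on which the research
question could be re-analyzed for cross-dataset validation: the dataset must
contain the outcome and exposure (or close proxies). An empty list is a
valid answer.

Question: {question}

Catalog:
{catalog}

Reply with a JSON object {"dataset_ids": [...]}.
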