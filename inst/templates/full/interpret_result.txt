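You are interpreting the output of an analysis script run for the research
question below. Summarize what the output shows, extract every named
quantitative result as a name-to-number mapping, and list anomalies
(warnings, suspicious values, missing outputs).

Question: {question}
Exit status: {exit_status}
stdout:
{stdout}
stderr:
{stderr}

Reply with a JSON object {"summary": ..., "quantities": {name: number, ...},
"anomalies": [...]}.
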