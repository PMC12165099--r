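Summarize this output for: {question} (exit {exit_status})
stdout: {stdout}
stderr: {stderr}
Reply with JSON {"summary":...,"quantities":{},"anomalies":[]}.
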