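Was the question answered? Question: {question}
Report: {summary} ({quantities})
Tail: {stdout_tail} Vars: {variables}/{confounders}
Reply with JSON {"question","variable","process","feedback","confidence"}.
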