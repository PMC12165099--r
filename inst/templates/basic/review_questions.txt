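Keep or reject each question.
{questions}
Reply with a JSON array of {"question_id","retained","reason"}.
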