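group,correct,incorrect,total
male,181,12,193
female,218,11,229
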