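true,non-frail/pre-frail,frail
non-frail/pre-frail,435,11
frail,0,84
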