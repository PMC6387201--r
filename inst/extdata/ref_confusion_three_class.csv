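true,non-frail,pre-frail,frail
non-frail,206,36,7
pre-frail,34,156,5
frail,4,2,78
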