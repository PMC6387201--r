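setup,n_trials,n_errors
five_beacons,192,12
eight_beacons,192,9
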