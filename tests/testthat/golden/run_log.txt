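simulated cohort 'WT-like', 20 neurons, seed 42
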