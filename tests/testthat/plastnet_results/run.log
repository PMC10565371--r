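simulated 31772 encounter rows for 129 individuals
simulated 31772 encounter rows for 129 individuals
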