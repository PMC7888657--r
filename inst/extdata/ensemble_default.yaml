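# Langevin ensemble defaults shipped with the calibrated parameter set.
sigma: 0.05
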