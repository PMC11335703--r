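# Primary analysis: NAWM NVU variables vs the 13-test battery, unadjusted
input: synthetic
roi: NAWM
cognition_mode: tests13
adjustment: none
missing: complete
n_permutations: 1000
seed: 1
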