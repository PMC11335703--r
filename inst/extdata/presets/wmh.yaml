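# Secondary region of interest: NVU variables measured in WMH
input: synthetic
roi: WMH
cognition_mode: tests13
adjustment: none
missing: complete
n_permutations: 1000
seed: 1
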