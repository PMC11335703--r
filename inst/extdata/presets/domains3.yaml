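# Sensitivity: 3 cognitive domain composites instead of 13 test scores
input: synthetic
roi: NAWM
cognition_mode: domains3
adjustment: none
missing: complete
n_permutations: 1000
seed: 1
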