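# Sensitivity: every variable residualized on age, sex, education
input: synthetic
roi: NAWM
cognition_mode: tests13
adjustment: age_sex_edu
missing: complete
n_permutations: 1000
seed: 1
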