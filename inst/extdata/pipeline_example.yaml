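# Example pipeline configuration
n_subjects: 500
seed: 1
k: 6
k_tests: 10
factor: 5
point_noise_sd: 0.5
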