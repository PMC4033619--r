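# Example run configuration for the criticgate command-line wrapper.
# Keys omitted here keep the package defaults; unknown keys are rejected.
n_sims: 100
n_trials: 100
accuracy_grid: [0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
noise_fraction: 0.4
modes: [plain, confidence]
confidence_rule: literal
master_seed: 11
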