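# Default simulation grid: every combination of k, nu and pattern below is
# run with `reps` replications. tau2 = nu * sigma2 throughout.
k: [3, 5, 7, 10, 100]
nu: [10, 1, 0.5, 0.1]
pattern: [balanced, one_large, one_small, mixture]
theta: 1
sigma2: 0.1
n_within: 30
reps: 10000
alpha: 0.05
seed: 42
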