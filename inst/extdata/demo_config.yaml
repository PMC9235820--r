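# Demo configuration for runPipeline(): a small synthetic oddball block.
out_dir: surprise-demo
trials: 80
p_deviant: 0.3333333333333333
channels: 4
samples: 20
center_ms: 250
width_ms: 50
beta0: 1.0
beta1: 0.5
noise_sd: 1.0
ar1_rho: 0.5
true_measure: shannon
true_w: 16
measures: [shannon]
regimes: [entire]
w_grid: [8, 16, 32]
folds: 5
permutations: 10
segments: detect
seed: 1
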