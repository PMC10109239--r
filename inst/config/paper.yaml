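# Full-scale run configuration (defaults made explicit)
profile: paper
eta: 0.8
K: 10
p: 5
lambda_l: 1.0e-5
lambda_d: 0.001
lambda_t: 0.001
hidden_dim: 500
embed_dim: 200
epochs: 5000
lr_repr: 1.0e-4
lr_gbdt: 0.02
n_rounds: 500
n_folds: 10
seed: 1
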