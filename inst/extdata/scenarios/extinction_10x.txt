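label = extinction 10x
lambda0 = 0.1
lambda1 = 0.1
mu0 = 0.3
mu1 = 0.03
q01 = 0.01
q10 = 0.01
n_tips = 500
n_reps = 500
seed = 1
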