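label = speciation high bias
lambda0 = 0.0843158908832
lambda1 = 0.118601605169
mu0 = 0.05
mu1 = 0.05
q01 = 0.005
q10 = 0.005
n_tips = 500
n_reps = 500
seed = 1
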