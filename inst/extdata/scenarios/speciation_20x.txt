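label = speciation 20x
lambda0 = 0.1
lambda1 = 2
mu0 = 0.03
mu1 = 0.03
q01 = 0.01
q10 = 0.01
n_tips = 500
n_reps = 500
seed = 1
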