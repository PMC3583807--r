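label = speciation low bias
lambda0 = 0.0935553091892
lambda1 = 0.106888642522
mu0 = 0.05
mu1 = 0.05
q01 = 0.005
q10 = 0.005
n_tips = 500
n_reps = 500
seed = 1
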