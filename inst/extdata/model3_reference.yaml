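# Reference configuration of the apoptosis-mediated co-culture model
# (variant III); rates in 1/hour, populations as fractions of N_max.
# The associated conserved macrophage total is M_c = 0.3.
variant: III
lambda_E: 1/72
lambda_M: 1/72
alpha: 100
K_1: 0.1
eta_me: 1/120
eta_em: 1/72
K_M0: 0.1
K_E0: 0.1
k: 4
"n": 2
m: 2
beta: 1/36
K_2: 1
beta_c: 1/1200
eta_1: 1/24
eta_2: 1/24
K_E: 0.1
K_M: 0.1
K_C: 1
eta_12: 1/72
eta_21: 1/72
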