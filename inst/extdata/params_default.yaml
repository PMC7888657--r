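# Calibrated cascade parameter set shipped with the package.
# Produced by multi-start capped least squares on the built-in knockout
# ratio table under structural (mono-/bistability) constraints; see
# calibrate_cascade() and the methods vignette.
henry_constant: 1200.0
K_L: 24.0
n_L: 2.0
K_NO2: 0.06
n_NO2: 1.0
beta_L: 1.0
beta_R: 1.0
alpha_K: 0.0330254
beta_K: 0.3179697
alpha_N: 0.027813
beta_N: 10.0
alpha_F: 0.0295094
beta_F: 2.5488526
delta: 1.0
K_RK: 0.0954533
A_K_dist: 1.4038921
A_N_dist: 1.1680382
A_K_fix: 1.6021251
A_N_fix: 0.0179816
rho_K: 100.0
rho_N: 1.0507936
n_DNA: 2.0
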