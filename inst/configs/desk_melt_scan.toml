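# Desk-scale melting scan used for development and tests: short stiff
# chains so the bundle -> dispersed transition is sharp at L = 20 within
# accessible run lengths; Langevin thermostat (small bundles are weakly
# ergodic under Nose-Hoover).
seed = 3

[model]
epsilon = 1.0
k_bend = 20.0

[melt]
N = 2
L = 20
T_min = 0.1
T_max = 1.9
T_step = 0.09
steps_per_T = 15000
thermostat = "langevin"
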