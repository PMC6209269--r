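# Desk-scale quench: 10 chains of L = 30 at the production volume fraction,
# fastest cooling rate (19,000 steps from T = 2 to 0.1).
seed = 31

[model]
epsilon = 1.0
k_bend = 0.7

[run]
N = 10
L = 30
phi = 2.61e-3
T_start = 2.0
T_end = 0.1
rate = 1e-4
thermostat = "langevin"
traj_every = 2000
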