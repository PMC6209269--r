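# Full-scale non-equilibrium network formation: 50 chains of L = 100 at
# bead volume fraction phi = 2.61e-3 (box ~ 100 sigma), quenched from
# T = 2 to T = 0.1.  Cooling rates used at full scale: 1e-7, 1e-5, 1e-4
# (temperature drop per time step); 12 randomly generated replicas.
# The source protocol states k_bend = 0.7 for this study while the bundle
# studies use 7.0 (a probable typo); both are exposed -- this file records
# the literal 0.7.
seed = 1

[model]
epsilon = 1.0
k_bend = 0.7

[run]
N = 50
L = 100
phi = 2.61e-3
T_start = 2.0
T_end = 0.1
rate = 1e-5
thermostat = "nose-hoover"
traj_every = 100000
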