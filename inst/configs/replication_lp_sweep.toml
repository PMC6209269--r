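# Full-scale bundle-rigidity sweep: relative persistence length lpr(N) at
# fixed L = 100 and T = 0.1, chain stiffness swept over the allowed values.
# Production run lengths (>= 1e8 steps, Nose-Hoover) -- NOT for the test
# suite; see desk_*.toml for desk-scale settings.
seed = 1

[model]
epsilon = 1.0
k_bend = 10.0
# sweep values: [4, 5, 7, 10, 20, 40, 60, 80]
# epsilon sweep for the interaction study: 0.8 - 1.8 (N = 4, k_bend = 7)

[run]
L = 100
# N sweep: [1, 2, 3, 4, 5, 8, 10, 16, 32]
N = 8
T = 0.1
thermostat = "nose-hoover"
n_steps = 100000000
sample_every = 50
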