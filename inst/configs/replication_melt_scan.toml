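# Full-scale bundle melting study: Ebond(T) = Ubond/Np heating scans for
# bundles of L = 100, k_bend = 7 chains; Tm from the derivative peak of the
# fitted sigmoid.  Temperature range 0.01 - 1.5 (the companion rigidity
# study quotes 0.1 - 1.5; both are valid here).
seed = 1

[model]
epsilon = 1.0
k_bend = 7.0

[melt]
# N sweep: [1, 2, 3, 4, 5, 8, 10, 16, 32]
N = 8
L = 100
T_min = 0.01
T_max = 1.5
T_step = 0.02
steps_per_T = 1000000
thermostat = "nose-hoover"
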