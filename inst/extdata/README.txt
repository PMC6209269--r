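lpr_crossover_synthetic.csv
  SYNTHETIC fixture: relative bundle persistence length lpr(N) generated
  from the crossover relation lpr = lpr_inf * N^2 / (lpr_inf - 1 + N^2)
  with lpr_inf = 6 plus Gaussian noise (sd = 0.12, seed = 2026) via
  polybundle::make_synthetic_curves("crossover-eq4"). Not simulation or
  experimental data; used by the CLI fit tests.
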