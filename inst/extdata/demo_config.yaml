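# Small synthetic demonstration run (see README and the methods vignette).
scenario:
  n_rows: 60
  n_cols: 60
  n_layers: 3
  autocorr_length: 4
  n_presences: 300
thin_km: 4
thin_trials: 10
rm_grid: [1, 1.5, 2]
background_n: 3000
enfa_background_n: 20000
n_boot: 300
seed: 11
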