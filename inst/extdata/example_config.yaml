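# Example two-condition simulation for `pol2wave simulate`.
# Control recycles efficiently; the depleted condition has reduced
# recycling probability and elongation velocity.
control:
  n_genes: 50
  k_init: 0.5
  k_release: 2
  v: 2000
  v_sd: 200
  term_dwell: 1
  rho: 0.9
  depth: 200000
  seed: 1
depleted:
  n_genes: 50
  k_init: 0.5
  k_release: 2
  v: 1200
  v_sd: 200
  term_dwell: 1
  rho: 0.2
  depth: 200000
  seed: 2
schedule:
  block_start: 0
  block_end: 60
  block_samples: [0, 10, 20, 40]
  washout_samples: [0, 10, 20, 40]
  burn_in: 60
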