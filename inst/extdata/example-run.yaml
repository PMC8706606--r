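# example run configuration: double repressilator at constant mid-window coupling
network:
  n_genes: 3
  topology: all_pairs
  gate: OR
  coupling_reverse: 0.1
schedule:
  kind: constant
  g_start: 0.15
integrator:
  t_max: 300
  n_out: 1500
seed: 11
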