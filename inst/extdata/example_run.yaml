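# Example pipeline configuration: a synthetic folded/unfolded mixture of
# the N9-aminated hairpin, analysed end to end.
topology:
  hairpin: true
  aminated: [9]
input:
  synth:
    state_mix:
      folded_II: 0.7
      frayed: 0.15
      unfolded: 0.15
    n_frames: 200
    jitter_sigma: 8
seed: 7
cluster_cutoff: 0.1
min_report: 0
output_dir: hairpin_reports
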