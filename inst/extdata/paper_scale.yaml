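# Paper-scale preset: the full simulated irradiation protocol.
# 12 capped 13-alanine peptides in two antiparallel sheets, 9,662 waters
# (30,690 atoms), 4,000 pulses at 35 ps spacing (140 ns).  This preset
# documents the full-scale study conditions; it is far beyond a desk-scale
# run and is not exercised by the test suite.
builder:
  sequence: "AAAAAAAAAAAAA"
  n_peptides: 12
  n_layers: 2
  strand_spacing: 4.8
  layer_spacing: 5.4
  n_waters: 9662
  box: 68.359
  seed: 1
forcefield:
  target_nu: 1680
  cutoff: 12
equilibrate:
  duration: 10000        # 10 ns
  temperature: 310
  minimize_steps: 500
spectrum:
  duration: 40000        # 40 ns
  equilibration: 10000
  segment_ps: 10
  sample_fs: 2
irradiate:
  E0: 1.0e8
  sigma: 1
  interval: 35
  n_pulses: 4000
  out_stride: 500
  field_mask: all
replica_seeds: [11, 12, 13, 14, 15, 16]
output: "fibrilpulse_paper_scale"
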