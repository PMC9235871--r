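# Demo configuration: the full 60-vine study block (6 NS rows x 10 vines,
# 2.4 x 1 m spacing) imaged at 2 cm GSD with the 50-band 500-900 nm grid.
# Water potentials are observed on a random 30-vine subset.
seed: 1
grid:
  n_bands: 50
  lambda_min: 500
  lambda_max: 900
  fwhm: 8
layout:
  n_rows: 6
  vines_per_row: 10
  gsd: 0.02
roi_side: 0.8
aggregation: index-mean
ecophys_subset: 30
cv_k: 3
ipls_widths: [10, 5]
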