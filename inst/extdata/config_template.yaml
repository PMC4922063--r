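# Pipeline configuration template. Every tunable of the analysis appears
# here with its default; values omitted from a user file fall back to
# these. Permutation counts are demonstration-scale; the full-scale
# analyses use 100000 genome-wide and 25000 chromosome-wide permutations.
seed: 1
litters:
  n_litters: 11
  penetrance_hom: 1.0
  penetrance_het: 0.0784313725490196   # 4/51
cohort:
  n_cases: 28
  n_controls: 73
  n_markers: 2000
  founder_haplotypes: 8
  penetrance_hom: 1.0
  penetrance_het: 0.0784313725490196
  missing_rate: 0.02
  switch_rate: 0.01
association:
  maf_min: 0.05
  call_rate_min: 0.75
  n_perm: 2000
haplotype:
  min_window: 2
  max_window: 10
  n_perm: 2000
variants:
  n_private_linked: 15
  n_shared_common: 50
  n_cases: 3
  n_controls: 3
  panel_size: 103
  missing_rate: 0.0
  panel_carries_causal: false
prioritize:
  strict_controls: false
  focus_region: PROMOTER
  promoter_length: 10000
exons:
  group_sizes: [3, 3]
  planted_fc:
    M: 11.5
  dispersion: 0.1
  mean_depth: 1.0e6
  fc_threshold: 2.0
promoter:
  ref_length: 8000
  motif_payload: GCTAACAAAGTTGC
  deletion_width: 96
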