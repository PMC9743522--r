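# Demo pipeline configuration: a simulated 6-sample cohort with one planted
# canonical-type (tandem duplication) fusion. All coordinates/bp.
fine: 10000
coarse: 50000
report: 500000
z_threshold: 4
min_effect: 0.15
exclusion_flank: 1000000
tolerance: 1000
min_size: 10000
min_callers: 2
seed: 42
simulate:
  n_samples: 6
  fusion_sample: 1
  fusion_type: tandem_duplication
  depth: 3000000
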