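# Study-1-style screen on a synthetic stand-in cohort: 17 positive / 39
# negative specimens, 10 scans each, binary screen swept over model sizes.
name: study1-synthetic
seed: 101
cohort:
  synthetic:
    n_per_class:
      BCA-positive: 17
      BCA-negative: 39
    scans_per_specimen: 10
classification:
  positive_class: BCA-positive
analysis:
  sweep: [1, 25]
signatures:
  space: dapc
  threshold: 0.3
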