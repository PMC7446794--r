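# Study-4-style multi-class screen: three clinic-type classes evaluated
# one-vs-rest (the other two classes counted as negative results).
name: study4-synthetic
seed: 104
cohort:
  synthetic:
    grid: [380, 1850, 2]
    n_per_class:
      Urology: 10
      Nephrology: 10
      Healthy: 10
    scans_per_specimen: 4
classification:
  positive_class: [Urology, Nephrology, Healthy]
analysis:
  n_pcs: 8
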