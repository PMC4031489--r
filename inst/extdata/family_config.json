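{
  "maf_threshold": 0.001,
  "sift_damaging_max": 0.05,
  "polyphen_damaging_min": 0.447,
  "kept_classes": ["nonsynonymous_SNV", "splicing", "stopgain", "stoploss"],
  "caller_mode": "intersection",
  "control_ids": ["3"],
  "recurrence_common_min": 2
}
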