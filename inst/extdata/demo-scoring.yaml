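# Example scale-scoring configuration for score_scales(): each scale
# names its items, reverse-coded items with the item response range, and
# the aggregation rule.
scales:
  mastery:
    items: [m1, m2, m3, m4, m5, m6, m7]
    reverse: [m2, m5]
    range: [1, 4]
    aggregate: sum
  perceived_stress:
    items: [ps1, ps2, ps3, ps4]
    aggregate: mean
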