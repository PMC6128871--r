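# Default band definitions and endpoint search windows, in cm^-1.
# These are defaults: endpoint windows should be reconciled with the band
# table established for your instrument and sample set before production use.
peaks:
  carb:    {nominal: 1030, left_window: [850, 1000],  right_window: [1080, 1180]}
  arom15:  {nominal: 1510, left_window: [1420, 1490], right_window: [1535, 1590]}
  arom16:  {nominal: 1630, left_window: [1535, 1590], right_window: [1690, 1780]}
  aliph28: {nominal: 2850, left_window: [2730, 2810], right_window: [2860, 2895]}
  aliph29: {nominal: 2920, left_window: [2860, 2895], right_window: [2950, 3050]}
silicate:
  # presence: minimum normalized corrected height (cm) for a diagnostic
  # mineral band to count as present; carb_large: the ~1030 cm^-1 peak is
  # "large" above this normalized height. Advisory screen, never deletion.
  thresholds: {presence: 3.0e-4, carb_large: 5.0e-3}
  bands:
    kaolinite_3695: {nominal: 3695, left_window: [3650, 3682], right_window: [3706, 3745]}
    kaolinite_3620: {nominal: 3620, left_window: [3560, 3600], right_window: [3634, 3655]}
    silicate_780:   {nominal: 780,  left_window: [725, 765],   right_window: [795, 835]}
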