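weights:
  walking: 20.0
  light_sport: 21.0
  moderate_sport: 23.0
  strenuous_sport: 23.0
  muscle_strength: 30.0
  light_housework: 25.0
  heavy_housework: 25.0
  home_repair: 30.0
  lawn_work: 36.0
  gardening: 20.0
  caring_for_others: 35.0
  work: 21.0
freq_midpoints:
  '0': 0.0
  '1': 1.5
  '2': 3.5
  '3': 6.0
dur_midpoints:
  '1': 0.5
  '2': 1.5
  '3': 3.0
  '4': 5.0
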