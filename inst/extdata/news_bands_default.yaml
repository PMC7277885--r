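# Default NEWS band table: Royal College of Physicians NEWS (2012).
# Intervals are closed on both printed endpoints; values are compared after
# rounding temperature to 0.1 degC and the other parameters to integers.
# Alternative local variants of the form can be supplied via read_news_bands().
respiration_rate:
  - {min: -.inf, max: 8, score: 3}
  - {min: 9, max: 11, score: 1}
  - {min: 12, max: 20, score: 0}
  - {min: 21, max: 24, score: 2}
  - {min: 25, max: .inf, score: 3}
spo2:
  - {min: -.inf, max: 91, score: 3}
  - {min: 92, max: 93, score: 2}
  - {min: 94, max: 95, score: 1}
  - {min: 96, max: 100, score: 0}
temperature:
  - {min: -.inf, max: 35.0, score: 3}
  - {min: 35.1, max: 36.0, score: 1}
  - {min: 36.1, max: 38.0, score: 0}
  - {min: 38.1, max: 39.0, score: 1}
  - {min: 39.1, max: .inf, score: 2}
systolic_bp:
  - {min: -.inf, max: 90, score: 3}
  - {min: 91, max: 100, score: 2}
  - {min: 101, max: 110, score: 1}
  - {min: 111, max: 219, score: 0}
  - {min: 220, max: .inf, score: 3}
heart_rate:
  - {min: -.inf, max: 40, score: 3}
  - {min: 41, max: 50, score: 1}
  - {min: 51, max: 90, score: 0}
  - {min: 91, max: 110, score: 1}
  - {min: 111, max: 130, score: 2}
  - {min: 131, max: .inf, score: 3}
supplemental_oxygen_score: 2
avpu_not_alert_score: 3
band_cutpoints:
  stable_max: 4
  unstable_max: 6
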