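# Default simulated-experiment configuration: two strains on a
# variable-interval 180 s schedule, five 90-min sessions of five
# 18-min segments. Parameter values match the shipped presets
# (shr_like_params() / wky_like_params()).
design:
  n_rats:
    SHR: 16
    WKY: 15
  n_sessions: 5
  session_duration_s: 5400
  n_segments: 5
  vi_mean_s: 180
strains:
  SHR:
    base_lever_rate: 18
    rat_rate_sd_log: 0.25
    segment_dispersion_sd_log: 0.35
    dispersion_trend_per_segment: 0.04
    burst_prob: 0.35
    burst_irt_mean_s: 0.30
    nonburst_irt_mean_s: 4
    incorrect_door_rate: 3
    incorrect_lever_frac: 0.25
  WKY:
    base_lever_rate: 10
    rat_rate_sd_log: 0.20
    segment_dispersion_sd_log: 0.15
    dispersion_trend_per_segment: -0.02
    burst_prob: 0.15
    burst_irt_mean_s: 0.35
    nonburst_irt_mean_s: 5
    incorrect_door_rate: 0.8
    incorrect_lever_frac: 0.15
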