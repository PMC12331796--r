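# Urgent flanker task with a flanker-target SOA of 0 or 120 ms:
# 6 participants x 5 sessions x 4 blocks of 264 trials (first block of
# session 1 is practice). The 120-ms SOA head start for the flankers creates a
# processing asymmetry: on incongruent trials the flankers drive the response
# in a window around 400 ms rPT, pushing accuracy below chance. The dip depth
# is calibrated at load time so the generative incongruent curve bottoms out
# at 0.16 (dip_target_min); the rise delay is larger than in exp1/exp2 because
# the conflict must be resolved before target-driven responses win.
design:
  n_participants: 6
  n_sessions: 5
  blocks_per_session: 4
  trials_per_block: 264
  gap_levels_ms: [0, 100, 200, 300, 400, 500, 600, 700, 800, 900, 950]
  fixation_levels_ms: [350, 400, 500]
  soa_levels_ms: [0, 120]
  deadline_ms: 1000
  practice_blocks: 1
observer:
  soa_models:
    "0":
      p_floor: 0.5
      hand_bias: 0.5
      p_asym: 0.93
      rise_mid_ms: 350
      rise_scale_ms: 60
      congruency_delay_ms: 50
      dip_depth: 0
      rt_mean_ms: 800
      rt_sd_ms: 150
      rt_min_ms: 100
      rt_max_ms: 1300
    "120":
      p_floor: 0.5
      hand_bias: 0.5
      p_asym: 0.93
      rise_mid_ms: 350
      rise_scale_ms: 60
      congruency_delay_ms: 150
      dip_center_ms: 400
      dip_width_ms: 80
      dip_target_min: 0.16
      rt_mean_ms: 800
      rt_sd_ms: 150
      rt_min_ms: 100
      rt_max_ms: 1300
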