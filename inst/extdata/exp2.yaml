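# Urgent flanker task, letter stimuli: identical design to exp1; the observer
# reaches a slightly lower asymptote (letters are harder than colors).
design:
  n_participants: 6
  n_sessions: 5
  blocks_per_session: 9
  trials_per_block: 132
  gap_levels_ms: [0, 100, 200, 300, 400, 500, 600, 700, 800, 900, 950]
  fixation_levels_ms: [350, 400, 500]
  soa_levels_ms: [0]
  deadline_ms: 1000
  practice_blocks: 1
observer:
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
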