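# Urgent flanker task, color stimuli: 6 participants x 5 sessions x 9 blocks
# of 132 trials (first block of session 1 is practice), gaps 0-950 ms in 11
# levels, 1,000-ms deadline, no flanker-target SOA.
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
# No-dip observer: congruent and incongruent tachometric curves differ only by
# a 50-ms delay of the incongruent rise (the flanker effect); no below-chance
# interval.
observer:
  p_floor: 0.5
  hand_bias: 0.5
  p_asym: 0.95
  rise_mid_ms: 350
  rise_scale_ms: 60
  congruency_delay_ms: 50
  dip_depth: 0
  rt_mean_ms: 800
  rt_sd_ms: 150
  rt_min_ms: 100
  rt_max_ms: 1300
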