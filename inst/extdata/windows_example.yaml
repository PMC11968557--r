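# Example time-frame layout for a two-scenario developmental exposure
# study (early start at 2 hpf with two concentration levels, late start at
# 24 hpf with two levels).  Frames sharing a span across scenarios are
# congruent; frames are half-open [start, end).
windows:
  - {label: A, start_hpf: 2,  end_hpf: 24, scenario: early, level: C_low}
  - {label: B, start_hpf: 24, end_hpf: 72, scenario: early, level: C_low}
  - {label: C, start_hpf: 72, end_hpf: 96, scenario: early, level: C_low}
  - {label: D, start_hpf: 2,  end_hpf: 24, scenario: early, level: C_medium}
  - {label: E, start_hpf: 24, end_hpf: 72, scenario: early, level: C_medium}
  - {label: F, start_hpf: 72, end_hpf: 96, scenario: early, level: C_medium}
  - {label: G, start_hpf: 24, end_hpf: 72, scenario: late,  level: C_medium}
  - {label: H, start_hpf: 72, end_hpf: 96, scenario: late,  level: C_medium}
  - {label: I, start_hpf: 24, end_hpf: 72, scenario: late,  level: C_high}
  - {label: J, start_hpf: 72, end_hpf: 96, scenario: late,  level: C_high}
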