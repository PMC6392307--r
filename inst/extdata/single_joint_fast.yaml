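experiment: single_joint_fast
controllers:
  - proposed
  - ep
  - optimal
delay_ms: 65
J: 0.0188
dt_ms: 1
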