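# UK TTO (MVH study) value set for EQ-5D-3L. Utilities are 1 minus the
# applicable decrements. Replaceable: point uk_tto_tariff(file=) at a file
# with the same keys to use another additive 3L value set.
constant_decrement: 0.081
level2_decrements:
  mobility: 0.069
  self_care: 0.104
  usual_activities: 0.036
  pain: 0.123
  anxiety: 0.071
level3_decrements:
  mobility: 0.314
  self_care: 0.214
  usual_activities: 0.094
  pain: 0.386
  anxiety: 0.236
n3_decrement: 0.269
unconscious_utility: -0.4
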