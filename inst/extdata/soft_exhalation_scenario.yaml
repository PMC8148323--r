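# Soft-exhalation counterfactual: a long puff with a gentle 1.8 s
# exhalation whose plume never reaches the bystander's breathing zone
# (zero direct transfer), so both secondhand doses are zero.
puff:
  kind: long_puff
  duration_s: 5.0
  volume_m3: 5.5e-05
  shape: half_sine
exhalation:
  duration_s: 1.8
room:
  direct_transfer_fraction: 0
window_s: 12
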