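# Worst-case secondhand scenario: high-flow post puff exhaled toward the
# bystander's face. Omitted keys take the package defaults (THC species,
# calibrated near-field, 0.5 g / 80% / 100-puff e-liquid).
puff:
  kind: post_puff
  duration_s: 1.34
  volume_m3: 5.5e-05
  shape: triangular
exhalation:
  duration_s: 2.5
room:
  volume: 27
  ventilation_flow: 0.018
breathing:
  minute_volume_m3: 6.0e-03
  period_s: 4
window_s: 12
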