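# Frozen near-field calibration constants.
#
# Produced once by scripts/calibrate_near_field.R, which runs
# calibrate_near_field() on the default post-puff scenario (default airway
# emission pulse, 6 L/min nasal breathing with a 4 s period, 12 s window)
# against the reference secondhand fractions (bystander inhales 5.9% and
# dermally absorbs 2.6% of the exhaled mass). See the methods vignette for
# the calibration rationale.

CALIBRATED_DIRECT_TRANSFER <- 0.8991330337
CALIBRATED_DEPOSITION_VELOCITY <- 1.4479448041e-3
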