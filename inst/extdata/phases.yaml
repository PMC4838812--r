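# Four-phase interictal-to-ictal scenario for run_phase_sequence().
# Gains in mV, durations in seconds.  A and all other model parameters
# take their standard defaults unless overridden at the top level.
A: 5
phases:
  - label: background
    duration: 5
    B: 45
    G: 20
  - label: sporadic_spiking
    duration: 5
    B: 38
    G: 20
  - label: sustained_spiking
    duration: 5
    B: 37
    G: 20
  - label: gamma
    duration: 5
    B: 8
    G: 20
# The ictal fifth phase changes G as well as B, but its published gain
# values are not machine-readable.  Uncomment and supply your own values
# at your own risk -- these placeholders are NOT validated against any
# reference:
#  - label: ictal
#    duration: 5
#    B: 15
#    G: 5
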