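# Small synthetic beverage panel for examples and quick CLI runs:
# 3 classes x 2 concentrations x 2 replicates, 10 s cycle at 30 Hz.
type: beverage
class_names: [beer, black_tea, red_wine]
concentrations: [0.25, 1.0]
replicates: 2
excitation:
  segment_frequencies: [1, 2]
  pulse_amplitudes: [1.0, 0.6, 0.2]
  cycle_duration: 10
  sampling_rate: 30
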