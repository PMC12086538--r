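# Example configuration: override only what differs from the defaults.
# Sections: budget, prices, bse, nbse, simulation.
bse:
  fertility: 0.66
  cow_bull_ratio: 25
nbse:
  fertility: 0.60
  cow_bull_ratio: 25
simulation:
  breeding_cycles: 3
  iterations: 200
  seed: 20250304
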