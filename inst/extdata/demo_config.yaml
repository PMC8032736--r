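# four-cell demo landscape: 31 fire years on a 2 x 2 grid of 50-km cells
nx: 2
ny: 2
years: {from: 1986, to: 2016}
fire_rate: 0.32
seed: 42
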