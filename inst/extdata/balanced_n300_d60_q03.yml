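# Balanced-dispersal scenario: 300 fish in the study reach (100 per zone),
# equal buffer density, movement range 60, baseline capture probability 0.3.
n_per_zone: 100
q0: 0.3
scheme: standard
delta: 60
bs_ratio: 1.0
n_iter: 10000
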