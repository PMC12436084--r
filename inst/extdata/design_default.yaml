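# Default design: 3 stages, 3 experimental arms + control, O'Brien-Fleming
# efficacy with zero interim futility, FWER 5%, conjunctive power 80%,
# standardized target effect 0.5, equal interim spacing.
K: 3
J: 3
shape: fixed_futility_obf
alpha: 0.05
power: 0.8
delta: 0.5
sigma: 1
spacing: I
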