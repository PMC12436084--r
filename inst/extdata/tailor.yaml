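# Dose-ranging illustration: 2-stage, 3 experimental arms + control,
# 42 patients per arm per stage (n_max = 336), 6-month outcome delay,
# recruitment horizons 29/24/20 months. Boundary shapes are re-calibrated
# in-package; the trial's own (unpublished) boundaries contribute only the
# fixed-size pipeline columns.
K: 3
J: 2
n: 42
m0: 6
tmax: [29, 24, 20]
shapes: [obf, pocock, triangular]
alpha: 0.05
power: 0.8
delta: 0.5
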