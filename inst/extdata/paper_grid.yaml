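# Full delay-sensitivity scenario grid: stages and arms 2-4, delays 0-36
# months against a 36-month recruitment period, uniform and linear
# recruitment, the three named interim spacings.
J: [2, 3, 4]
K: [2, 3, 4]
m0: [0, 6, 12, 18, 24, 30, 36]
tmax: 36
models: [uniform, linear]
spacings: [I, II, III]
shapes: [fixed_futility_obf]
tau: alternative
alpha: 0.05
power: 0.8
delta: 0.5
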