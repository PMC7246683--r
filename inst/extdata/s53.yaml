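# Scenario s53: joint cross-channel transmission sweep in the coexistence
# demand regime. The source prints a second "beta22" list for what its prose
# describes as the beta21 sweep; it is swept here as beta21, with beta22 held
# at its stated value 1e-05. Same gamma/r reading as s51.
r1: 1
r2: 1
K1: 1000
K2: 1000
m: -0.8
"n": -0.5   # quoted: a bare n is YAML 1.1 shorthand for false
beta11: 2.0e-05
beta12: 5.0e-06   # swept jointly with beta21
beta21: 3.0e-06
beta22: 1.0e-05
gamma1: 0.01
gamma2: 0.01
N1_0: 100
I1_0: 1
N2_0: 100
I2_0: 1
t_end: 10
sweep:
  beta12: [5.0e-06, 1.0e-05, 2.0e-05, 5.0e-05]
  beta21: [3.0e-06, 1.0e-05, 2.0e-05, 5.0e-05]
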