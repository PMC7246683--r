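# Scenario s52: online transmission sweep; channel 2 wins the demand
# competition. Same reading of the published "gamma = 1 then gamma = 0.01"
# lists as in s51: r1 = r2 = 1, gamma1 = gamma2 = 0.01.
r1: 1
r2: 1
K1: 1000
K2: 1000
m: -1.2
"n": -0.5   # quoted: a bare n is YAML 1.1 shorthand for false
beta11: 5.0e-05
beta12: 5.0e-05
beta21: 5.0e-05
beta22: 5.0e-06   # swept: 5e-06, 3e-05, 6e-05, 9e-05
gamma1: 0.01
gamma2: 0.01
N1_0: 100
I1_0: 1
N2_0: 100
I2_0: 1
t_end: 10
sweep:
  beta22: [5.0e-06, 3.0e-05, 6.0e-05, 9.0e-05]
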