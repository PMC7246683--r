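# Scenario s51: offline transmission sweep under a bistable demand regime.
# The published parameter list opens with "gamma1 = gamma2 = 1" and later
# assigns "gamma1 = gamma2 = 0.01"; the first assignment is read here as the
# intrinsic growth rates r1 = r2 = 1 (the only reading consistent with the
# stated check R1 = beta11*K1/gamma1 = 0.5 at beta11 = 5e-06).
r1: 1
r2: 1
K1: 1000
K2: 1000
m: -1.2
"n": -1.5   # quoted: a bare n is YAML 1.1 shorthand for false
beta11: 5.0e-06   # swept: 5e-06, 3e-05, 6e-05, 9e-05
beta12: 0.05
beta21: 0.05
beta22: 0.05
gamma1: 0.01
gamma2: 0.01
N1_0: 100
I1_0: 1           # seed purchasers: not published; I = 0 would stay at 0
N2_0: 100
I2_0: 1
t_end: 300
sweep:
  beta11: [5.0e-06, 3.0e-05, 6.0e-05, 9.0e-05]
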