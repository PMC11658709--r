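k1: 0.03
k11: 0.0046
k12: 0.0056
k2: 0.25
k3a: 0.7
k4: 0.24
k41: 0.0008
k42: 0.0036
k5: 0.095
k6a: 0.6
k6b: 0.43
Dr: 30.0
Dg: 8.0
Dd: 12.0
rho_Rmax: 200.0
rho_Dmax: 40.0
L: 40.0
N_Rac1: 7300.0
N_GAP: 1600.0
N_DGAP1: 1100.0
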