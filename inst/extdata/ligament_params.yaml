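C1: 5000000.0
D: 1.0e-09
k1: 2.06e+07
k2: 0.201
k: 0.0
lambda0: 1.183
lambdaC: 1.35
beta: 0.00019
gFloor: 0.25
isochoric: yes
damageVolumetric: no
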