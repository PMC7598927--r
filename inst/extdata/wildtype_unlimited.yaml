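# Wildtype configuration, unlimited repair capacity (R = inf).
# g, Q, P_div are the repository base calibration: fixed once so that a
# damage-free founder at (k1 = 0.4, re = 0.2957) divides exactly 24 times
# in both capacity regimes (see the methods vignette).
g: 1.92
k1: 0.4
k2: 0.092
Q: 0.478
R: inf
re: 0.2957
s: 0.64
P_div: 0.5
D_death: 1.0
D_health: 0.5
sigma: 0.005
founders: 5
founder_D0: 0.0
max_generation: 2
max_cells: 4000
max_divisions: 1000
max_lifetime: 10000.0
target_rls: 24
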