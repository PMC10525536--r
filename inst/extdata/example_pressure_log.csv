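bottle_id,time_min,abs_pressure_psi,cum_pressure_psi
D1_S1,0,0,0
D1_S1,10,0.31,0.31
D1_S1,20,0.62,0.62
D1_S1,30,0.18,0.93
D1_S1,40,0.49,1.24
D1_S1,50,0.05,1.55
D1_S1,60,0.36,1.86
D1_B1,0,0,0
D1_B1,10,0.05,0.05
D1_B1,20,0.09,0.09
D1_B1,30,0.12,0.12
D1_B1,40,0.14,0.14
D1_B1,50,0.15,0.15
D1_B1,60,0.15,0.15
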