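region,n_F1,k_A,k_B
Alabama_R1,1,1,0
Florida_R2,109,35,74
Georgia_R3,7,0,7
Georgia_R5,4,2,2
South_Carolina_R6,4,1,3
Virginia_R7,2,0,2
Virginia_R8,26,2,24
Virginia_R9,16,7,9
Georgia_R10,18,0,18
total,187,48,139
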