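np,beam,cell_line,scenario,n_per_cell,zbar_Gy,dxi_lo,dxi_hi,dalpha_ratio_printed,der_printed
AGuIX,250kVp,SQ20B,1,6.06e8,8.2e-4,0.027,0.078,0.034,1.025
AGuIX,250kVp,SQ20B,1,6.06e9,8.2e-4,0.27,0.78,0.34,1.25
AGuIX,250kVp,SQ20B,2,6.06e8,6.4e-4,0.020,0.059,0.025,1.019
AGuIX,250kVp,SQ20B,2,6.06e9,6.4e-4,0.20,0.59,0.25,1.19
AGuIX,250kVp,SQ20B,3,6.06e8,9.1e-4,0.031,0.089,0.038,1.027
AGuIX,250kVp,SQ20B,3,6.06e9,9.1e-4,0.31,0.89,0.38,1.27
AuNP,220kVp,Hela,1,6000,2.0e-3,0.93,0.93,0.25,1.24
AuNP,220kVp,Hela,1,18000,2.0e-3,2.8,2.8,0.76,1.71
AuNP,220kVp,Hela,2,6000,1.7e-3,0.75,0.75,0.21,1.20
AuNP,220kVp,Hela,2,18000,1.7e-3,2.3,2.3,0.62,1.59
AuNP,220kVp,Hela,3,6000,2.6e-3,1.20,1.20,0.33,1.30
AuNP,220kVp,Hela,3,18000,2.6e-3,3.6,3.6,0.98,1.91
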