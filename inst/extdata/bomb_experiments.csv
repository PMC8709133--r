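id,cell_line,np,beam,n_per_cell,alpha,sigma_alpha,alpha_np,sigma_alpha_np,beta,beta_np,p1_printed,sf_printed,sf_np_printed,rbe_printed
SQ20B_AGuIX_250kVp,SQ20B,AGuIX,250kVp,6.06e8,0.04,NA,0.5,NA,0.05,0.03,0.015,0.76,0.33,2.17
A549_AGuIX_250kVp_low,A549,AGuIX,250kVp,1.66e7,0.332,0.045,0.349,0.054,0.018,0.018,NA,0.48,0.46,1.04
A549_AGuIX_250kVp_pHLIP,A549,AGuIX,250kVp,1.32e9,0.332,0.045,0.488,0.063,0.018,0.018,2.34e-3,0.48,0.35,1.37
Hela_AuNP_105kVp,Hela,AuNP,105kVp,6000,0.237,0.005,0.528,0.007,0.041,0.054,1.64e-3,0.53,0.28,1.69
Hela_AuNP_220kVp,Hela,AuNP,220kVp,6000,0.150,0.004,0.352,0.005,0.041,0.041,1.73e-3,0.63,0.42,1.56
Hela_AuNP_Cs137,Hela,AuNP,Cs137,6000,0.119,0.013,0.259,0.011,0.040,0.030,0.436,0.67,0.53,1.39
Hela_AuNP_6MV,Hela,AuNP,6MV,6000,0.110,0.008,0.191,0.002,0.029,0.031,1.11,0.71,0.60,1.35
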