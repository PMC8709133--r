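reference,np_description,beam,cell_type,alpha,alpha_np,beta,beta_np
Chithrani2010,50 nm Gold NP 6000 per cell,105kVp,HeLa,0.237,0.528,0.041,0.054
Chithrani2010,50 nm Gold NP 6000 per cell,220kVp,HeLa,0.150,0.352,0.041,0.041
Chithrani2010,50 nm Gold NP 6000 per cell,Cs137,HeLa,0.119,0.259,0.040,0.030
Chithrani2010,50 nm Gold NP 6000 per cell,6MVp,HeLa,0.110,0.191,0.029,0.031
Jain2011,1.9 nm Gold NP 12 uM,160kVp,MDA-MB-231,0.019,0.091,0.052,0.093
Jain2011,1.9 nm Gold NP 12 uM,6MV,MDA-MB-231,0.002,0.104,0.079,0.098
Jain2011,1.9 nm Gold NP 12 uM,15MV,MDA-MB-231,0.083,0.061,0.059,0.121
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,AGO-1552B,0.25,0.30,0.04,0.05
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,Astro,0.37,0.40,0.08,0.09
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,DU-145,0.03,0.05,0.04,0.04
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,L132,0.12,0.11,0.03,0.03
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,MCF-7,0.46,0.28,0.02,0.07
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,MDA-231-MB,0.09,0.15,0.03,0.03
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,PC-3,0.12,0.29,0.06,0.03
Butterworth2010,1.9 nm Gold NP 10 ug/mL,160kVp,T98G,0.04,0.14,0.03,0.02
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,AGO-1552B,0.25,0.68,0.04,0.04
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,Astro,0.37,0.23,0.08,0.16
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,DU-145,0.03,0.04,0.04,0.04
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,L132,0.12,0.05,0.03,0.04
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,MCF-7,0.46,0.24,0.02,0.08
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,MDA-231-MB,0.09,0.27,0.03,0.02
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,PC-3,0.12,0.21,0.06,0.03
Butterworth2010,1.9 nm Gold NP 100 ug/mL,160kVp,T98G,0.04,0.06,0.03,0.02
Stefancikova2016,AGuIX 0.5 mM,1.25MV,U87,0.4,0.71,0.03,0
Miladi2015,AGuIX 0.6 mM,250kVp,SQ20B,0.04,0.5,0.05,0.03
Miladi2015,AGuIX 0.6 mM,250kVp,FaDu,0.01,0.2,0.08,0.07
Miladi2015,AGuIX 0.6 mM,250kVp,Cal33,-0.05,0.07,0.08,0.11
Miladi2015,AGuIX 0.4 mM,250kVp,SQ20B,0.04,0.15,0.05,0.05
Kotb2016,AGuIX 0.6 mg/L,220kVp,B16F10,0.056,0.275,0.025,0.022
Stewart2016,Bi2O3 NP 50 ug/mL,125kVp,9L gliosarcoma,0.075,0.355,0.017,0
Stewart2016,Bi2O3 NP 50 ug/mL,10MV,9L gliosarcoma,0.150,0.256,0.013,0.009
Wozny2017,AGuIX 0.8 mg/mL,250kVp,SQ20B,0.07,0.19,0.03,0.04
Simonet2020,AGuIX 0.8 mM Gd,250kVp,SQ20B J.L.,0.1593,0.2357,0.0079,0.0088
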