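np,beam,lambda,sigma_lambda,mu,sigma_mu,p1Gy,sigma_p1Gy
AGuIX,250kVp,0.168,0.003,3.00e-7,0.06e-7,5.04e-8,0.14e-8
AuNP,105kVp,46.1,0.9,6.41e-4,0.13e-4,2.96e-2,0.08e-2
AuNP,220kVp,47.7,1.0,4.09e-4,0.08e-4,1.95e-2,0.05e-2
AuNP,Cs137,5.97,0.12,8.96e-6,0.18e-6,5.35e-5,0.15e-5
AuNP,6MV,2.63,0.05,4.63e-6,0.09e-6,1.22e-5,0.03e-5
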