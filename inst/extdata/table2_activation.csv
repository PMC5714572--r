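nuclide,sigma_parent_b,half_life_h,beta_emax_mev,beta_yield_pct,gamma_kev,gamma_yield_pct
90Y,1.28,64.1,2.284,100,NA,NA
90mY,0.001,3.19,NA,NA,480,90.0
153Sm,206.00,46.7,0.817,21.0,103,28.3
31Si,0.107,2.62,1.492,99.9,1270,0.07
28Al,0.231,0.0373333,2.864,100,1780,100
19O,0.00016,0.00747222,4.819,56.1,1360,50.3
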