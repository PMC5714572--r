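nuclide,half_life_h,emax_mev,beta_yield_pct,emean_mev,parent_abundance_pct,gamma_kev,gamma_yield_pct,sigma_parent_b
90Y,64.0,2.284,100,0.934,100,NA,NA,1.28
90Sr,254938,0.546,100,0.196,NA,NA,NA,NA
32P,343.2,1.710,100,0.695,100,NA,NA,0.172
186Re,90.6,1.076,73.0,0.35,37.4,137,8.65,112
188Re,17.0,2.119,71.6,0.764,62.6,155,14.9,76.4
153Sm,46.7,0.817,21.0,0.228,26.75,103,28.3,206
142Pr,19.1,2.159,96.3,0.809,100,1580,3.7,11.5
177Lu,161.04,0.497,78.6,0.133,2.59,208,11.0,2090
166Ho,26.8,1.856,51.0,0.667,100,80.6,6.2,64.7
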