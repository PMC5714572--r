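element,weight_pct,mass_mg,molar_mass_g_mol,z,i_ev,parent_isotope,parent_abundance,product_nuclide
Y,43.2,3.722,88.906,39,379,89Y,1.0,90Y
O,34.7,2.994,15.999,8,95,18O,0.00205,19O
Si,14.0,1.203,28.085,14,173,30Si,0.0309,31Si
Al,7.9,0.679,26.982,13,166,27Al,1.0,28Al
152Sm,0.2,0.02,151.92,62,574,152Sm,1.0,153Sm
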