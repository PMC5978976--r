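material,energy_keV,mu_over_rho,mu_en_over_rho,density
Al,10,26.23,25.43,2.699
Al,15,7.955,7.487,2.699
Al,20,3.441,3.094,2.699
Al,30,1.128,0.8778,2.699
Al,40,0.5685,0.3601,2.699
Al,50,0.3681,0.1840,2.699
Al,60,0.2778,0.1099,2.699
Al,80,0.2018,0.05511,2.699
Al,100,0.1704,0.03794,2.699
Al,150,0.1378,0.02827,2.699
Cu,10,215.9,150.2,8.96
Cu,15,74.05,52.1,8.96
Cu,20,33.79,25.1,8.96
Cu,30,10.92,8.12,8.96
Cu,40,4.862,3.60,8.96
Cu,50,2.613,1.92,8.96
Cu,60,1.593,1.14,8.96
Cu,80,0.7630,0.490,8.96
Cu,100,0.4584,0.261,8.96
Cu,150,0.2217,0.102,8.96
air,10,5.120,4.742,0.0012049
air,15,1.614,1.334,0.0012049
air,20,0.7779,0.5389,0.0012049
air,30,0.3538,0.1537,0.0012049
air,40,0.2485,0.06833,0.0012049
air,50,0.2080,0.04098,0.0012049
air,60,0.1875,0.03041,0.0012049
air,80,0.1662,0.02407,0.0012049
air,100,0.1541,0.02325,0.0012049
air,150,0.1356,0.02496,0.0012049
soft_tissue,10,5.367,4.964,1.06
soft_tissue,15,1.693,1.396,1.06
soft_tissue,20,0.8205,0.5641,1.06
soft_tissue,30,0.3783,0.1610,1.06
soft_tissue,40,0.2685,0.07192,1.06
soft_tissue,50,0.2262,0.04349,1.06
soft_tissue,60,0.2048,0.03258,1.06
soft_tissue,80,0.1823,0.02615,1.06
soft_tissue,100,0.1693,0.02544,1.06
soft_tissue,150,0.1492,0.02745,1.06
table_composite,10,26.23,25.43,2.699
table_composite,15,7.955,7.487,2.699
table_composite,20,3.441,3.094,2.699
table_composite,30,1.128,0.8778,2.699
table_composite,40,0.5685,0.3601,2.699
table_composite,50,0.3681,0.1840,2.699
table_composite,60,0.2778,0.1099,2.699
table_composite,80,0.2018,0.05511,2.699
table_composite,100,0.1704,0.03794,2.699
table_composite,150,0.1378,0.02827,2.699
pad_foam,10,5.367,4.964,0.03
pad_foam,15,1.693,1.396,0.03
pad_foam,20,0.8205,0.5641,0.03
pad_foam,30,0.3783,0.1610,0.03
pad_foam,40,0.2685,0.07192,0.03
pad_foam,50,0.2262,0.04349,0.03
pad_foam,60,0.2048,0.03258,0.03
pad_foam,80,0.1823,0.02615,0.03
pad_foam,100,0.1693,0.02544,0.03
pad_foam,150,0.1492,0.02745,0.03
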