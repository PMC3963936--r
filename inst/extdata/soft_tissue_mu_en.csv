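# medium=soft_tissue density_g_cm3=1.05
# Mass energy-absorption coefficients mu_en/rho (cm2/g) for soft tissue
# (water-equivalent), abridged from the standard NIST-style photon compilations.
# Log-log linear interpolation is applied between grid points.
energy_keV,mu_en_rho_cm2_g
2,615
3,192
4,82.0
5,41.9
6,24.1
8,9.92
10,4.94
15,1.37
20,0.536
30,0.152
40,0.0670
50,0.0410
60,0.0310
80,0.0258
100,0.0252
150,0.0276
200,0.0297
300,0.0319
500,0.0330
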