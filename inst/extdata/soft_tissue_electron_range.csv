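# medium=soft_tissue density_g_cm3=1.05
# Electron collision stopping power and CSDA range in soft tissue (water-equivalent),
# abridged from the standard NIST-style stopping-power compilations.  Ranges are mass
# ranges (g/cm2); divide by density for path length.  Log-log monotone interpolation
# is applied between grid points.
energy_keV,stopping_power_MeV_cm2_g,csda_range_g_cm2
1,126.0,4.40e-06
2,77.5,1.54e-05
3,56.9,3.19e-05
4,45.8,5.40e-05
5,38.9,8.14e-05
6,34.1,1.14e-04
8,27.4,1.92e-04
10,22.6,2.515e-04
15,16.5,5.147e-04
20,13.2,8.566e-04
30,9.65,1.756e-03
40,7.78,2.919e-03
50,6.60,4.320e-03
60,5.80,5.940e-03
80,4.80,9.773e-03
100,4.12,1.431e-02
125,3.59,2.060e-02
150,3.24,2.817e-02
175,2.98,3.667e-02
200,2.79,4.487e-02
300,2.36,8.420e-02
400,2.15,1.289e-01
500,2.03,1.766e-01
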