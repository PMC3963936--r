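# nuclide=Tc-99m half_life_h=6.0067
# Principal discrete emissions of Tc-99m per nuclear transformation, curated from the
# standard MIRD/ICRP-107 decay-data compilations.  Continuous Auger cascades are
# represented by their mean-energy discrete lines; lines carry >= 99% of emitted energy.
# kind: photon | electron ; energy in keV ; yield in emissions per decay.
kind,energy_keV,yield
photon,140.511,0.885
photon,142.63,0.000233
photon,18.367,0.0404
photon,18.251,0.0213
photon,20.62,0.0124
photon,2.42,0.0075
electron,1.63,0.746
electron,2.05,0.231
electron,119.467,0.0879
electron,137.49,0.0107
electron,139.97,0.00216
electron,140.43,0.00044
electron,121.59,0.0047
electron,139.6,0.0009
electron,15.35,0.0155
electron,17.82,0.0074
electron,20.27,0.0012
electron,2.02,0.105
electron,0.43,1.20
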