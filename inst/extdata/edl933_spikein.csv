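# Spike-in validation measurements: E. coli O157:H7 strain EDL933 added to soil
# at six levels (treatments E9..E4). nominal_added = genomes per g dry soil
# (1 mL of a 2.1e11..2.1e6 CFU/mL suspension into 30 g soil; 1 CFU = 1 genome).
# marker_quant = fliC gene copies per g dry soil by qPCR (mean of triplicates,
# marker_sd its SD). ihaaq = Escherichia-Shigella absolute abundance, copies per
# g dry soil, from relative abundance x total 16S copies in the given region.
treatment,nominal_added,marker_quant,marker_sd,region,ihaaq,ihaaq_sd
E9,7.0e9,4.79e9,1.30e9,V3,4.67e10,9.07e8
E8,7.0e8,5.96e8,1.20e7,V3,3.59e9,2.20e8
E7,7.0e7,5.28e7,1.40e6,V3,2.94e8,1.17e7
E6,7.0e6,5.70e6,4.62e5,V3,2.82e7,3.86e6
E5,7.0e5,5.65e5,5.19e4,V3,3.48e6,2.83e4
E4,7.0e4,8.11e4,3.15e3,V3,1.47e6,7.66e4
E9,7.0e9,4.79e9,1.30e9,V4,4.82e10,1.09e9
E8,7.0e8,5.96e8,1.20e7,V4,4.37e9,3.53e8
E7,7.0e7,5.28e7,1.40e6,V4,3.39e8,1.13e7
E6,7.0e6,5.70e6,4.62e5,V4,4.08e7,2.52e6
E5,7.0e5,5.65e5,5.19e4,V4,6.47e6,2.07e5
E4,7.0e4,8.11e4,3.15e3,V4,3.14e6,1.25e5
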