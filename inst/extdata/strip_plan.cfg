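# Strip-sown treatment: high-density baited bands with unbaited gaps
pattern = strip
sowing_rate_kg_ha = 10
fps_m = 75
swath_m = 10
toxin_conc = 0.0002
mean_bait_mass_g = 6
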