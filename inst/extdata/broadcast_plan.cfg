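# Broadcast treatment: complete, uniform coverage
pattern = broadcast
sowing_rate_kg_ha = 30
fps_m = 25
swath_m = 25
toxin_conc = 0.0002
mean_bait_mass_g = 6
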