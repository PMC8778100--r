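variable,value
lai,1.8
fsolar_obs,0.7
biomass_per_plant,40
harvest_index,0.3
initial_fsolar,0.01
fsolar_max,0.94
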