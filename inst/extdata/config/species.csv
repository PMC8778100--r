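variable,value
tbase,10
topt,26
maxt,35
extremet,40
co2rue,0.09
s_water,0
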