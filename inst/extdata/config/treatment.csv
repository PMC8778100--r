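variable,value
weather,weather_{region}.csv
co2,400
sowing_date,FD
cycle_cap,200
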