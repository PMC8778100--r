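region,tsum,rue,observed_yield
Apartado,2906,0.6,3378
Arauca,2764,0.7,3981
Santander,2016,0.6,2687
Cali,1912,0.5,1900
Caldas,1192,0.6,740
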