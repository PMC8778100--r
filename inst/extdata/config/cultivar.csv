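cultivar,i50a,i50b
ICS95,680,680
CCN51,680,680
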