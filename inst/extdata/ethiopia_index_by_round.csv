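year,eci,prevalence_pct
2005,0.251,19.8
2011,0.239,25.9
2016,0.201,27.9
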