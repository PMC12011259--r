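species,a,b,c,carbon_fraction,root_shoot_ratio
Cunninghamia lanceolata,0.1,2.4,,0.5,0.25
Robinia pseudoacacia,0.12,2.35,,0.5,0.26
Pinus tabulaeformis,0.09,2.45,,0.5,0.24
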