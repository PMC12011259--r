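stratum_id,area_weight,stock_sd
broadleaf,0.6,20
conifer,0.4,30
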