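plot,biomass_t,carbon_sink_measured_t,carbon_sink_predicted_t
1,55.08,21.24,NA
2,56.58,21.65,22.26
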