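quantity,value
recruited,1229
evaluable,875
progressors,139
median_mgfr_baseline,48.1
median_mgfr_followup,43.6
median_age_baseline,67.1
n_men,505
n_women,370
extra_mgfr_12m,215
extra_mgfr_24m,188
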