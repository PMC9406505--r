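method,accuracy_pct,distance_mean_mm,distance_sd_mm
reference_internal,88.11,5.543,6.310
ours_internal,88.82,5.333,6.240
reference_external,87.33,5.668,6.651
ours_external,90.67,5.015,5.147
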