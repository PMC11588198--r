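operating_point,sensitivity_pct,specificity_pct
outcome_algorithm,84.2,31.3
murmur_algorithm,55.5,77.4
clinician,42.3,88.9
random,78.3,21.7
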