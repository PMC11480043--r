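model,waist_actual_cm,deg10,deg15,deg20,deg30,deg45,deg60
M12,6.1,6.18,6.18,6.16,6.10,5.98,5.89
M14,6.6,6.99,7.02,6.87,6.81,6.54,6.41
M15,7.3,7.12,7.13,7.07,7.06,6.92,6.80
M16,7.6,7.53,7.52,7.51,7.48,7.31,7.30
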