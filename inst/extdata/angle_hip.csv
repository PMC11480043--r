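model,hip_actual_cm,deg10,deg15,deg20,deg30,deg45,deg60
M12,8.1,8.88,8.88,8.80,8.69,8.37,8.12
M14,8.6,9.53,9.53,9.45,9.22,8.96,8.49
M15,9.8,9.82,9.88,9.80,9.64,9.39,9.06
M16,10.1,10.19,10.19,10.12,9.99,9.73,9.28
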