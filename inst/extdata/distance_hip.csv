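model,hip_actual_cm,measured_25cm,error_25cm_pct,measured_30cm,error_30cm_pct,measured_40cm,error_40cm_pct
M12,8.1,8.81,8.80,8.98,10.90,8.85,9.25
M13,9.2,9.29,0.96,9.47,2.95,9.37,1.84
M14,8.6,9.52,10.67,9.49,10.38,9.29,8.03
M15,9.8,9.56,2.47,9.73,0.70,9.67,1.32
M16,10.1,10.06,0.43,10.11,0.09,10.14,0.37
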