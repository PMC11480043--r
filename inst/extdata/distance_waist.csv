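model,waist_actual_cm,measured_25cm,error_25cm_pct,measured_30cm,error_30cm_pct,measured_40cm,error_40cm_pct
M12,6.1,6.00,1.62,5.00,1.70,6.33,3.84
M13,7.1,6.65,6.37,6.81,4.09,6.66,6.18
M14,6.6,6.55,0.69,6.66,0.85,6.59,0.22
M15,7.3,6.83,6.50,6.94,4.97,7.01,4.03
M16,7.6,7.27,4.39,7.30,4.02,7.43,2.29
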