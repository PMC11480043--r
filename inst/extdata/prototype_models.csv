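model,height_cm,waist_actual_cm,waist_measured_cm,waist_error_pct,hip_actual_cm,hip_measured_cm,hip_error_pct
M1,18,8.5,8.16,4.02,11.5,11.38,1.02
M2,9.8,4.5,4.20,6.69,6,5.94,0.97
M3,10,6,5.91,1.55,8,7.70,3.77
M4,10,4.7,4.60,2.15,6.5,6.09,6.35
M5,11,7.5,6.97,7.09,8,7.64,4.53
M6,18,8,7.81,2.43,11.5,11.48,0.20
M7,16.5,8,7.57,5.40,11,10.93,0.63
M8,14,5.5,4.97,9.56,8.5,8.07,5.11
M9,14,4,3.91,2.37,6.5,6.68,2.74
M10,11,5,4.85,2.91,7.3,6.74,7.66
M11,11,4,3.67,8.16,5,4.97,0.61
M12,15,6.1,6.08,0.26,8.1,8.76,8.20
M13,15,7.1,6.60,7.04,9.2,9.07,1.45
M14,15,6.6,6.58,0.28,8.6,9.32,9.60
M15,15,7.3,6.90,5.46,9.8,10.01,2.10
M16,15,7.6,7.35,4.58,10.1,10.08,0.17
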