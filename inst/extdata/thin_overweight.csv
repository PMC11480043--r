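model,waist_actual_cm,waist_measured_cm
skinny,4.7,4.47
overweight,6,5.95
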