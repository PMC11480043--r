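quantity,waist_cm,hip_cm
actual,7.60,10.10
cosine,7.29,10.11
ellipse,7.22,9.34
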