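interval_deg,side_cm
0-30,0.39
30-60,0.36
60-90,0.31
90-120,0.30
120-150,0.35
150-180,0.38
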