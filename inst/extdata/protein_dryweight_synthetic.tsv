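protein_g_per_l	dryweight_g_per_l
0.05	0.118
0.10	0.221
0.15	0.312
0.20	0.415
0.25	0.509
0.30	0.618
0.35	0.711
0.40	0.808
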