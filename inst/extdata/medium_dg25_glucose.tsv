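reaction	lower	upper
EX_glc	-25	1000
EX_h2o	-1000	1000
EX_pi	-1000	1000
EX_nh4	-1000	1000
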