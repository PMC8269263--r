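substrate	exchange	observed_growth
glucose	EX_glc	TRUE
cellobiose	EX_clb	TRUE
cellulose	EX_cel	TRUE
xylose	EX_xyl	FALSE
dextran	NA	FALSE
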