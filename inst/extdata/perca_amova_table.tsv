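source	df	ss	variance_component	pct_variation
among_populations	3	334.462	0.784	7.44
within_populations	532	5188.229	9.752	92.56
total	535	5522.690	10.536	NA
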