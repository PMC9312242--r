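pop_a	pop_b	d	fst	significant
WR	JL	0.205	0.087	TRUE
WR	WL	0.157	0.071	TRUE
WR	KR	0.288	0.158	TRUE
JL	WL	0.027	0.003	FALSE
JL	KR	0.244	0.116	TRUE
WL	KR	0.1987	0.100	TRUE
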