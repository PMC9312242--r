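locus	forward	reverse	repeat_motif	n_repeats	size_min	size_max
HLJHL007	GCTAATGCCTGACCACCACT	CAGGTCCCTGGAGAAGAGAGA	ACAG	10	109	130
HLJHL022	CCCTGAGTGGAGCACATACC	GGCCGAATTTTGCCTTTGTA	ACAG	12	100	131
HLJHL045	GATGGTCTCACGAGGCTAGC	TCGGTTTGGATGGTCGGTTT	ACAG	14	86	114
HLJHL052	ACCTGAAGGCAAGTGGATGG	CCTGGCCCTGAATGTACCAA	ACAG	15	92	120
HLJHL056	CAGCAGCCTGATCAGCATCA	TGCTTTACTTCCTCATCACAGC	ACAG	15	120	148
HLJHL059	GGTTTCAAGGGAGAGGGAGG	GCAGCTCATGAACAACTCTGC	ACAG	15	92	145
HLJHL084	AGCTCGACTAGGGTGACTGT	CCGAGCACTGCTACGAAACT	ACAG	18	143	174
HLJHL089	ATTCACACAAACAAGCAGGC	GCTATGTGGCTCTTTGTATGCC	ACAG	19	100	160
HLJHL090	GGCGCTGTCCATGGTACTAA	ACCACGAAAAGCAAGAAGGC	ACAG	19	117	162
HLJHL094	ACTCACCATACGCATGTGCT	CTCCTCAAAGTCGCCTTCCA	ACAG	19	114	186
HLJHL104	CCCAAATTTCCTGACAACCCA	GGACTGTCCCGTGTTTCTCA	AGAT	10	132	223
HLJHL105	GCGCGATAAAATAATTGTCGGC	TCAGGCTCAGGAATTTCTTTCA	AGAT	10	107	148
HLJHL107	AGACAGGGTGATAGTTACATCCA	TGTGCAAAATTTACATGGGATGA	AGAT	10	118	188
HLJHL121	ATTGGCATCAGAGCAAGCTG	ATGGGGCTTTGACGTGAGAG	AGAT	11	184	265
HLJHL152	GCCAACACCCTATAACTGAAGC	CGTTGTTGCCAATGGAATGC	AGAT	14	140	185
HLJHL153	GGCTGATAAACATAGGCCTATGC	AGCTACTGGGATCTTGAAGGT	AGAT	14	123	151
HLJHL164	CCACCTCTGCCACCTCATAC	CGAAGGGATCTCCATCTGCT	AGAT	15	104	175
HLJHL165	TCCAGTTGTCACTTCAGCGT	AGGACACATTTCCTTCGGGA	AGAT	15	88	194
HLJHL167	CGTTTTGGATATGTGCCATGT	TGGCACATATCTAAAACGTGGT	AGAT	15	140	188
HLJHL169	GCAGGGGCAAACAGTCATCA	TCTGTGAGCTACTGGGACCT	AGAT	16	100	152
HLJHL172	ACAGCCCATAACACAGCAGT	TCTGCATGAACTAAAGTGTGACA	AGAT	16	126	187
HLJHL174	TCAGCTGCGGATTATTACACA	GCAGTGATATTGCAACAGGAAA	AGAT	16	131	162
HLJHL179	GGTGATACATAGATAGGTAGGTCGG	TCTGGTAGTCTCAGCTCGCT	AGAT	16	96	153
HLJHL183	TGTTGTCAGTGTGTTCATCCA	TGCATGGTGTTTTAAGTCAGGG	AGAT	17	125	168
HLJHL186	CAACCAGCTTCAACCCGTTG	TCCACCTCTCCCTTTCCCTT	AGAT	17	123	237
HLJHL189	CCTCCTGTGTTTTGTGTCTTGG	TCTCCAGTACTCACAATGGCT	AGAT	18	124	175
HLJHL192	TGGTTCTACAAGCTGCCTAAA	AACCAGGCGTTGAGTTTCAA	AGAT	18	102	168
HLJHL196	TCTGAGACAAAGGGACATGAAT	CAGGAATTTCCCCAGTGTGG	AGAT	19	111	183
HLJHL199	TGGACTAAGACTGCCTACTGC	CCTTGAGTTCACTTGCGTGT	AGAT	20	134	190
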