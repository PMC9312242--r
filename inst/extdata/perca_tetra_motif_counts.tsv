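motif	count
AGAT	1556
ACAG	1339
ATCC	752
AAAT	645
AAAG	610
ACAT	560
AATC	485
ACGC	442
AGGG	430
AATG	302
AAGG	234
AAAC	221
AAGT	201
ACTC	173
ACTG	135
AACT	127
AGGC	107
AGCT	101
AGCC	75
AATT	69
AACC	52
ACCT	40
ACCC	37
ATGC	22
ACCG	9
AAGC	8
AGCG	7
ATCG	4
ACGG	3
CCCG	2
ACGT	2
CCGG	1
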