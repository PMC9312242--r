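locus	na	ne	ho	he	pic
HLJHL007	4	2.201	0.403	0.547	0.489
HLJHL022	6	2.169	0.496	0.540	0.450
HLJHL045	8	2.133	0.485	0.532	0.496
HLJHL052	4	1.784	0.425	0.440	0.364
HLJHL056	5	2.827	0.623	0.647	0.578
HLJHL059	10	4.444	0.675	0.776	0.741
HLJHL084	9	1.310	0.239	0.237	0.225
HLJHL089	11	2.264	0.489	0.559	0.528
HLJHL090	11	1.671	0.373	0.402	0.389
HLJHL094	18	3.057	0.623	0.674	0.661
HLJHL104	17	7.506	0.869	0.868	0.853
HLJHL105	11	7.389	0.847	0.866	0.850
HLJHL107	18	9.968	0.896	0.901	0.892
HLJHL121	19	10.077	0.877	0.902	0.893
HLJHL152	13	5.949	0.791	0.833	0.811
HLJHL153	8	4.181	0.716	0.762	0.725
HLJHL164	14	5.863	0.776	0.831	0.809
HLJHL165	20	3.269	0.608	0.695	0.650
HLJHL167	13	6.486	0.519	0.847	0.827
HLJHL169	9	3.256	0.690	0.694	0.641
HLJHL172	15	4.677	0.750	0.788	0.765
HLJHL174	9	4.714	0.731	0.789	0.760
HLJHL179	11	3.273	0.612	0.696	0.658
HLJHL183	12	3.973	0.698	0.750	0.720
HLJHL186	29	10.914	0.694	0.910	0.901
HLJHL192	14	5.783	0.694	0.829	0.808
HLJHL196	15	2.389	0.526	0.583	0.512
HLJHL199	16	9.361	0.843	0.895	0.884
HLJHL200	15	6.564	0.813	0.849	0.833
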