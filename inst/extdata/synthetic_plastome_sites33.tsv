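site_id	chrom	position	strand	gene	codon_number	codon_position
rpoA-C67	synthPt	249	+	rpoA	67	2
psbZ-C50	synthPt	498	+	psbZ	50	2
atpF-C31	synthPt	901	+	atpF	31	2
ndhB-C50	synthPt	1148	+	ndhB	50	2
ndhB-C156	synthPt	1466	+	ndhB	156	2
ndhB-C196	synthPt	1586	+	ndhB	196	2
ndhB-C204	synthPt	1609	+	ndhB	204	1
ndhB-C246	synthPt	1736	+	ndhB	246	2
ndhB-C249	synthPt	1745	+	ndhB	249	2
ndhB-C277	synthPt	1829	+	ndhB	277	2
ndhB-C419	synthPt	2255	+	ndhB	419	2
ndhB-C494	synthPt	2479	+	ndhB	494	1
clpP-C30	synthPt	2702	-	clpP	30	2
rps14-C27	synthPt	3122	-	rps14	27	1
rps14-C50	synthPt	3052	-	rps14	50	2
matK-C167	synthPt	3898	+	matK	167	1
matK-C211	synthPt	4031	+	matK	211	2
ndhD-C1	synthPt	6099	-	ndhD	1	2
ndhD-C128	synthPt	5718	-	ndhD	128	2
ndhD-C200	synthPt	5503	-	ndhD	200	1
ndhD-C293	synthPt	5223	-	ndhD	293	2
ndhD-C437	synthPt	4792	-	ndhD	437	1
rpoB-C113	synthPt	6487	+	rpoB	113	2
rpoB-C158	synthPt	6622	+	rpoB	158	2
rpoB-C184	synthPt	6699	+	rpoB	184	1
rpoB-C334	synthPt	7150	+	rpoB	334	2
rpoC1-C21	synthPt	7561	+	rpoC1	21	2
ndhF-C97	synthPt	8411	-	ndhF	97	2
accD-C58	synthPt	8922	+	accD	58	2
rpl23-C89	synthPt	9136	-	rpl23	89	1
psbE-C72	synthPt	9634	+	psbE	72	2
psbF-C26	synthPt	9775	-	psbF	26	1
ndhG-C17	synthPt	9919	+	ndhG	17	2
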