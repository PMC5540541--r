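dataset	rank	forward	reverse	p_combined
2014	1	AGGTA	TACCT	3.12E-10
2014	2	TCGCA	TGCGA	2.69E-08
2014	3	ACGGC	GCCGT	5.51E-05
2014	4	CGCAG	CTGCG	7.31E-05
2014	5	ACCTG	CAGGT	0.000101
2014	6	CACAG	CTGTG	0.000158
2014	7	CCGAG	CTCGG	0.000240
2014	8	CCGGC	GCCGG	0.000451
2014	9	TCGAA	TTCGA	0.001007
2014	10	TGGAA	TTCCA	0.002042
2014	11	AGCCA	TGGCT	0.002623
2014	12	CCGCC	GGCGG	0.002625
2014	13	CTCAG	CTGAG	0.003514
2014	14	CACGA	TCGTG	0.003707
2014	15	ACATG	CATGT	0.003755
2014	16	CAGTA	TACTG	0.004126
2014	17	CCCAG	CTGGG	0.004429
2014	18	GCGAA	TTCGC	0.005546
2014	19	CCGAC	GTCGG	0.006022
2014	20	ACTCA	TGAGT	0.007033
2016	1	AGGTA	TACCT	1.24262E-11
2016	2	TCGCA	TGCGA	2.6884E-08
2016	3	CACAG	CTGTG	2.97136E-06
2016	4	CCGAG	CTCGG	2.11333E-05
2016	5	CCCAG	CTGGG	2.24424E-05
2016	6	ACGGC	GCCGT	5.50895E-05
2016	7	CGCAG	CTGCG	7.3056E-05
2016	8	ACCTG	CAGGT	0.000101
2016	9	CAGTA	TACTG	0.000287
2016	10	CTCAG	CTGAG	0.000431
2016	11	CCGGC	GCCGG	0.000451
2016	12	CCGCC	GGCGG	0.000482
2016	13	GCGAA	TTCGC	0.000508
2016	14	ACATG	CATGT	0.000538
2016	15	CCGAC	GTCGG	0.000630
2016	16	TGGAA	TTCCA	0.000657
2016	17	AGCCA	TGGCT	0.000802
2016	18	TCGAA	TTCGA	0.001007
2016	19	ACTCA	TGAGT	0.001370
2016	20	AGGTG	CACCT	0.002439
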