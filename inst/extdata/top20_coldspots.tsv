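dataset	rank	forward	reverse	p_combined
2014	1	AAAGA	TCTTT	3.23E-09
2014	2	AAAAA	TTTTT	5.80E-09
2014	3	AGAAA	TTTCT	6.82E-09
2014	4	AAAAT	ATTTT	1.07E-08
2014	5	GAAAA	TTTTC	1.68E-08
2014	6	AAGAA	TTCTT	3.88E-08
2014	7	GAAGA	TCTTC	6.47E-07
2014	8	AGAAG	CTTCT	1.08E-06
2014	9	GGAGA	TCTCC	1.22E-06
2014	10	TGAAA	TTTCA	1.56E-06
2014	11	GGAAA	TTTCC	1.70E-06
2014	12	TGAAG	CTTCA	3.03E-06
2014	13	CAAAA	TTTTG	4.40E-06
2014	14	GAAAT	ATTTC	4.48E-06
2014	15	GAAAG	CTTTC	1.38E-05
2014	16	AAAAC	GTTTT	1.40E-05
2014	17	TCAGA	TCTGA	1.62E-05
2014	18	AGAAT	ATTCT	1.92E-05
2014	19	CAAAG	CTTTG	2.29E-05
2014	20	CAGTG	CACTG	2.45E-05
2016	1	AAAGA	TCTTT	9.36858E-09
2016	2	AAAAT	ATTTT	1.07478E-08
2016	3	AAAAA	TTTTT	1.36135E-08
2016	4	AGAAA	TTTCT	1.77502E-08
2016	5	GAAAA	TTTTC	4.49683E-08
2016	6	GAAGA	TCTTC	6.47074E-07
2016	7	GGAGA	TCTCC	1.21713E-06
2016	8	AAGAA	TTCTT	1.26841E-06
2016	9	GGAAA	TTTCC	3.0346E-06
2016	10	TGAAA	TTTCA	3.83943E-06
2016	11	CAAAA	TTTTG	4.40191E-06
2016	12	TGAAG	CTTCA	8.86768E-06
2016	13	AGAAG	CTTCT	1.34215E-05
2016	14	TCAGA	TCTGA	1.62237E-05
2016	15	CAAAG	CTTTG	2.2854E-05
2016	16	GAAAG	CTTTC	2.88886E-05
2016	17	GAAAT	ATTTC	2.91218E-05
2016	18	AGAAT	ATTCT	4.88009E-05
2016	19	CAGAA	TTCTG	5.60054E-05
2016	20	AAACA	TGTTT	7.23417E-05
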