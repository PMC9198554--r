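chrom	set1	set2	set3	set4	total	avg_dist_mbp	max_dist_mbp	at_specific	g_specific	nonspecific
1A	9	0	0	10	19	29.68	46.30	19	0	0
1B	16	2	5	4	27	24.62	57.59	0	27	0
1D	7	1	1	3	12	38.11	164.34	2	9	1
2A	17	1	1	8	27	27.89	67.47	24	1	2
2B	25	2	5	2	34	22.89	62.09	0	33	1
2D	10	0	2	2	14	43.46	136.34	2	11	1
3A	11	0	2	13	26	27.81	61.95	26	0	0
3B	17	2	2	22	43	18.85	75.71	0	41	2
3D	7	0	3	3	13	43.97	181.60	2	11	0
4A	12	2	4	10	28	25.68	99.25	22	3	3
4B	14	2	1	7	24	26.94	66.91	1	23	0
4D	3	1	3	1	8	56.65	228.68	2	4	2
5A	11	5	5	11	32	21.51	60.90	32	0	0
5B	18	1	4	9	32	21.61	83.29	0	31	1
5D	11	0	0	1	12	43.54	204.45	5	7	0
6A	8	2	1	10	21	28.09	70.81	19	0	2
6B	17	2	1	8	28	24.86	61.64	0	27	1
6D	9	1	4	2	16	27.86	97.57	2	8	6
7A	10	3	2	9	24	29.47	118.70	24	0	0
7B	9	3	3	11	26	27.80	61.86	0	26	0
7D	9	0	2	3	14	42.58	133.02	0	13	1
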