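dataset	gene	cuffdiff	edger_glm	edger_exact	deseq2	qpcr
human_hippocampus	SERPINE1	1.41	1.71	1.54	0.98	1.66
human_hippocampus	TAC1	-1.77	-1.65	-1.85	-1.56	-0.42
human_hippocampus	ID2	0.98	1.07	0.88	-0.73	1.17
human_hippocampus	GRM2	0.86	0.98	0.78	0.63	0.44
human_hippocampus	LINC01314	-0.25	-1.19	-1.38	-1.05	-0.50
human_hippocampus	RP11-87E22.2	3.63	2.01	1.85	1.31	2.30
mouse_cortex	Vax1	-2.12	-2.02	-1.74	-1.71	-3.18
mouse_cortex	Caly	1.93	1.79	2.08	2.09	2.10
mouse_cortex	Igf2bp1	-9.40	-8.72	-8.45	-8.16	-5.61
mouse_cortex	Draxin	-5.98	-5.26	-4.98	-4.94	-6.80
mouse_cortex	Nrp1	-2.17	-2.22	-1.94	-1.92	-2.46
mouse_cortex	Ttr	11.04	11.18	11.46	11.28	11.63
mouse_cortex	Mobp	12.44	12.08	12.36	12.24	12.69
mouse_cortex	Wipf1	2.22	1.74	2.02	2.03	1.71
rat_liver	Bax-AFL	1.78	1.86	1.75	1.96	2.62
rat_liver	Cdkn1a-AFL	4.19	4.28	3.30	8.00	23.50
rat_liver	Myc-AFL	0.97	1.03	0.82	0.99	2.10
rat_liver	Met-AFL	-1.02	-0.94	-0.88	-0.89	-1.90
rat_liver	Bax-NIT	1.62	1.22	1.19	1.25	1.98
rat_liver	Cdkn1a-NIT	3.22	2.82	2.56	3.05	8.07
rat_liver	Figf-NIT	4.18	3.76	3.51	3.72	10.27
rat_liver	Fzd4-NIT	-0.30	-0.70	-0.69	-0.73	-2.07
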