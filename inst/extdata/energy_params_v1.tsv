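param	key1	key2	value
stack	AU	AU	-0.9
stack	AU	UA	-1.1
stack	AU	CG	-2.2
stack	AU	GC	-2.1
stack	AU	GU	-0.6
stack	AU	UG	-1.4
stack	UA	AU	-1.3
stack	UA	UA	-0.9
stack	UA	CG	-2.4
stack	UA	GC	-2.1
stack	UA	GU	-1
stack	UA	UG	-1.3
stack	CG	AU	-2.1
stack	CG	UA	-2.1
stack	CG	CG	-3.3
stack	CG	GC	-2.4
stack	CG	GU	-1.4
stack	CG	UG	-2.1
stack	GC	AU	-2.4
stack	GC	UA	-2.2
stack	GC	CG	-3.4
stack	GC	GC	-3.3
stack	GC	GU	-1.5
stack	GC	UG	-2.5
stack	GU	AU	-1.3
stack	GU	UA	-1.4
stack	GU	CG	-2.5
stack	GU	GC	-2.1
stack	GU	GU	-0.5
stack	GU	UG	-0.4
stack	UG	AU	-1
stack	UG	UA	-0.6
stack	UG	CG	-1.4
stack	UG	GC	-1.5
stack	UG	GU	-0.2
stack	UG	UG	-0.5
hairpin	3	NA	5.4
hairpin	4	NA	5.9
hairpin	5	NA	6.29
hairpin	6	NA	6.61
hairpin	7	NA	6.88
hairpin	8	NA	7.12
hairpin	9	NA	7.32
hairpin	10	NA	7.51
hairpin	11	NA	7.67
hairpin	12	NA	7.83
hairpin	13	NA	7.97
hairpin	14	NA	8.1
hairpin	15	NA	8.22
hairpin	16	NA	8.33
hairpin	17	NA	8.44
hairpin	18	NA	8.54
hairpin	19	NA	8.63
hairpin	20	NA	8.72
hairpin	21	NA	8.81
hairpin	22	NA	8.89
hairpin	23	NA	8.96
hairpin	24	NA	9.04
hairpin	25	NA	9.11
hairpin	26	NA	9.18
hairpin	27	NA	9.25
hairpin	28	NA	9.31
hairpin	29	NA	9.37
hairpin	30	NA	9.43
bulge	1	NA	3.8
bulge	2	NA	5.01
bulge	3	NA	5.72
bulge	4	NA	6.23
bulge	5	NA	6.62
bulge	6	NA	6.94
bulge	7	NA	7.21
bulge	8	NA	7.44
bulge	9	NA	7.65
bulge	10	NA	7.83
bulge	11	NA	8
bulge	12	NA	8.15
bulge	13	NA	8.29
bulge	14	NA	8.42
bulge	15	NA	8.54
bulge	16	NA	8.65
bulge	17	NA	8.76
bulge	18	NA	8.86
bulge	19	NA	8.95
bulge	20	NA	9.04
bulge	21	NA	9.13
bulge	22	NA	9.21
bulge	23	NA	9.29
bulge	24	NA	9.36
bulge	25	NA	9.43
bulge	26	NA	9.5
bulge	27	NA	9.57
bulge	28	NA	9.63
bulge	29	NA	9.69
bulge	30	NA	9.75
internal	2	NA	4.1
internal	3	NA	4.71
internal	4	NA	5.14
internal	5	NA	5.47
internal	6	NA	5.75
internal	7	NA	5.98
internal	8	NA	6.18
internal	9	NA	6.36
internal	10	NA	6.51
internal	11	NA	6.66
internal	12	NA	6.79
internal	13	NA	6.91
internal	14	NA	7.02
internal	15	NA	7.12
internal	16	NA	7.22
internal	17	NA	7.31
internal	18	NA	7.4
internal	19	NA	7.48
internal	20	NA	7.55
internal	21	NA	7.63
internal	22	NA	7.7
internal	23	NA	7.76
internal	24	NA	7.83
internal	25	NA	7.89
internal	26	NA	7.95
internal	27	NA	8
internal	28	NA	8.06
internal	29	NA	8.11
internal	30	NA	8.16
multiloop	a	NA	3.4
multiloop	b	NA	0.4
multiloop	c	NA	0
init	duplex	NA	4.1
extrapolation	coef	NA	1.75
maxloop	interior	NA	30
minloop	hairpin	NA	3
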