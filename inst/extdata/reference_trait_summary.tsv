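trait	unit	mean	sd	cv_pct	H2
DBH	mm	53.2	7.9	14.8	0.52
height	dm	67.1	4.1	6.1	0.42
volume	m3	0.016	0.005	31.3	0.53
bud_flush	Julian_days	87.4	7.8	8.9	0.90
leaf_C	pct_DW	44.4	1.6	3.6	0.09
leaf_N	pct_DW	3.2	0.3	9.4	0.28
leaf_CN	kgC_per_kgN	14.2	1.3	9.2	0.33
leaf_Delta	permil	19.2	0.7	3.6	0.26
leaf_d15N	permil	2.5	0.4	16.0	0.25
SLA	m2_per_kgDW	12.0	1.5	12.5	0.27
NArea	gN_per_m2	2.8	0.4	14.3	0.28
C5_sugars	pct	36.0	2.2	6.1	0.07
C6_sugars	pct	42.3	3.3	7.8	0.08
lignin	pct	22.7	1.0	4.4	0.15
SG_ratio	fold	1.9	0.1	5.3	0.58
galactonic_acid	RA	0.6	0.4	62.8	0.22
galactinol	RA	144.1	75.0	52.0	0.28
alpha_tocopherol	RA	69.3	31.1	44.9	0.16
adenosine	RA	2.8	1.0	33.4	0.25
hydroxybenzoic_acid	RA	5.9	4.6	78.3	0.45
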