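chrom	size_mbp	n_snps	bp_per_snp	ld_decay_kbp
Chr01	50.5	100299	503.4	29.99
Chr02	25.3	47563	531.1	27.49
Chr03	21.8	49962	436.7	27.19
Chr04	24.3	47671	509.1	22.36
Chr05	25.9	52236	495.6	23.35
Chr06	27.9	49374	565.3	27.21
Chr07	15.6	30295	515.3	18.85
Chr08	19.5	43099	451.6	21.99
Chr09	12.9	29287	442.1	21.63
Chr10	22.6	46758	482.9	24.21
Chr11	18.5	38563	479.8	51.63
Chr12	15.8	31964	493.1	25.13
Chr13	16.3	30493	535.2	28.07
Chr14	18.9	40482	467.4	29.65
Chr15	15.3	33418	457.2	18.85
Chr16	14.5	32006	452.9	26.22
Chr17	16.1	39114	411.1	33.83
Chr18	17.0	34049	498.1	33.39
Chr19	15.9	36647	435.0	19.26
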