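variant_id	gene	type	or	raf	raf_source
DRB1*01:01	HLA-DRB1	hla	1.29	0.070	synthetic
DRB1*09:01	HLA-DRB1	hla	1.20	0.140	synthetic
DRB1*10:01	HLA-DRB1	hla	2.88	0.005	synthetic
DRB1*04:01	HLA-DRB1	hla	1.89	0.010	synthetic
DRB1*04:04	HLA-DRB1	hla	1.49	0.003	synthetic
DRB1*04:05	HLA-DRB1	hla	2.31	0.130	synthetic
rs3093024	CCR6	snp	1.25	0.450	synthetic
rs2240340	PADI4	snp	1.23	0.400	synthetic
rs2736340	BLK	snp	1.24	0.700	synthetic
rs4810485	CD40	snp	0.80	0.250	synthetic
rs26232	C5orf30	snp	0.86	0.600	synthetic
rs2073838	SLC22A4	snp	1.14	0.800	synthetic
rs11676922	AFF3	snp	1.11	0.550	synthetic
rs7528684	FCRL3	snp	1.11	0.650	synthetic
rs934734	SPRED2	snp	1.14	0.450	synthetic
rs7574865	STAT4	snp	1.10	0.330	synthetic
rs3087243	CTLA4	snp	0.92	0.300	synthetic
rs3761847	TRAF1	snp	1.05	0.550	synthetic
rs706778	IL2RA	snp	1.05	0.400	synthetic
rs10499194	TNFAIP3	snp	1.18	0.080	synthetic
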