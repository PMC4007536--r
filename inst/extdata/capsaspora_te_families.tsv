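family	class	copies_min	copies_max	n_fle	n_solo	n_itr5	n_itr3	rnaseq_reads	identical_copies	ltr_id_min	ltr_id_max	pi_total	pi_fle	pi_solo	tajimas_d	d_significant
Cocv1	LTR	64	64	39	25	NA	NA	437027	47	99.3	100	0.075	0.011	0.160	-2.439	yes
Cocv2	LTR	33	33	23	10	NA	NA	22365	21	99.3	100	0.008	0.007	0.009	-2.396	yes
Cocv3	LTR	26	26	16	10	NA	NA	72753	15	100	100	0.021	0.012	0.033	-2.118	yes
Cocv4	LTR	17	17	1	16	NA	NA	80	2	100	100	0.174	0.000	0.184	-2.103	yes
Cocv5	LTR	22	22	14	8	NA	NA	62990	4	99.7	100	0.042	0.043	0.042	-1.526	no
CoL1	nonLTR	12	12	NA	NA	NA	NA	15275	0	NA	NA	0.048	NA	NA	-0.183	no
CoL2	nonLTR	51	51	NA	NA	NA	NA	63284	16	NA	NA	0.069	NA	NA	-1.478	no
CoL3	nonLTR	30	30	NA	NA	NA	NA	777	0	NA	NA	0.164	NA	NA	-1.925	yes
CoL4	nonLTR	47	47	NA	NA	NA	NA	49002	5	NA	NA	0.102	NA	NA	-2.186	yes
Cobalt1	DNA	17	34	NA	NA	17	17	29065	16	NA	NA	0.013	NA	NA	0.326	no
Cobalt2	DNA	9	18	NA	NA	9	9	8902	4	NA	NA	0.032	NA	NA	0.262	no
Cobalt3	DNA	1	1	NA	NA	NA	NA	805	0	NA	NA	NA	NA	NA	NA	no
CoCACTA1	DNA	18	18	9	NA	9	18	2629	4	NA	NA	0.028	NA	NA	0.210	no
CoCACTA2	DNA	35	35	NA	NA	20	24	1344	9	NA	NA	0.086	NA	NA	NA	no
Com1	DNA	19	19	NA	NA	15	16	26930	12	NA	NA	0.015	NA	NA	1.669	no
Com2	DNA	12	12	NA	NA	8	5	4941	0	NA	NA	0.197	NA	NA	-1.297	no
Cop1	DNA	28	51	NA	NA	23	28	65112	20	NA	NA	0.004	NA	NA	-2.078	yes
Cop2	DNA	25	44	NA	NA	19	25	56126	17	NA	NA	0.081	NA	NA	1.135	no
Cop3	DNA	15	27	NA	NA	12	15	46819	11	NA	NA	0.047	NA	NA	-2.003	yes
Cop4	DNA	19	37	NA	NA	19	18	32779	17	NA	NA	0.011	NA	NA	-1.405	no
Cop5	DNA	16	31	NA	NA	16	15	457	5	NA	NA	0.171	NA	NA	-1.518	no
CoTc1	DNA	42	83	NA	NA	41	42	164264	34	NA	NA	0.007	NA	NA	-2.669	yes
CoTc2	DNA	8	14	NA	NA	6	8	1566	0	NA	NA	0.022	NA	NA	-1.124	no
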