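metabolite	ppm	multiplicity	identified	comparison	es	es_error	p_value	fdr_ns	age_flag	dietary
2-Phosphoglycerate	4.43	m	TRUE	HG_vs_LG	-1.6	1.3	2.8e-2	TRUE	FALSE	FALSE
3-HBA	1.20	d	TRUE	PDA_vs_HG	1.5	1.2	5.0e-2	TRUE	FALSE	FALSE
3-HIBA	1.08	d	TRUE	PDA_vs_HG	1.4	1.2	2.2e-2	TRUE	FALSE	FALSE
3-Methylxanthine	8.03	s	TRUE	HG_vs_LG	-2.9	1.6	5.1e-3	FALSE	FALSE	FALSE
Alanine	1.48	d	TRUE	LG_vs_N	-4.6	2.2	2.5e-5	FALSE	FALSE	FALSE
Alanine	1.48	d	TRUE	PDA_vs_HG	1.4	1.2	3.8e-2	TRUE	FALSE	FALSE
AMP	8.60	s	TRUE	HG_vs_LG	-1.5	1.3	2.5e-2	TRUE	FALSE	FALSE
Ascorbate	4.51	d	TRUE	PDA_vs_HG	-1.4	1.2	4.2e-2	TRUE	FALSE	FALSE
Aspartate	2.80	d	TRUE	LG_vs_N	3.6	1.8	2.8e-3	FALSE	FALSE	FALSE
Aspartate	2.80	d	TRUE	HG_vs_LG	-2.2	1.5	3.1e-2	TRUE	FALSE	FALSE
Creatine	3.04	s	TRUE	LG_vs_N	-3.6	1.8	1.3e-4	FALSE	FALSE	FALSE
Glucose	5.23	d	TRUE	LG_vs_N	2.3	1.5	4.1e-2	TRUE	FALSE	FALSE
Glucose	5.23	d	TRUE	HG_vs_LG	1.6	1.3	3.9e-2	TRUE	FALSE	FALSE
Glucose	5.23	d	TRUE	PDA_vs_HG	-3.6	1.8	2.3e-3	FALSE	FALSE	FALSE
Glutamate	2.35	m	TRUE	LG_vs_N	5.0	2.3	7.3e-4	FALSE	FALSE	FALSE
Glutamate	2.35	m	TRUE	HG_vs_LG	-2.8	1.6	1.9e-3	FALSE	FALSE	FALSE
GPC	4.33	m	TRUE	HG_vs_LG	-1.9	1.4	3.7e-2	FALSE	FALSE	FALSE
Histidine	7.05	s	TRUE	LG_vs_N	-2.1	1.4	3.1e-2	TRUE	FALSE	FALSE
Lactate	1.33	d	TRUE	PDA_vs_HG	1.9	1.3	1.7e-2	TRUE	FALSE	FALSE
Lysine	1.70	m	TRUE	LG_vs_N	-1.8	1.3	2.5e-2	FALSE	FALSE	FALSE
m-Inositol	4.06	t	TRUE	LG_vs_N	2.3	1.5	2.6e-2	FALSE	FALSE	FALSE
m-Inositol	4.06	t	TRUE	HG_vs_LG	1.8	1.4	4.6e-2	TRUE	TRUE	FALSE
PC	4.17	m	TRUE	LG_vs_N	-4.4	2.1	3.7e-4	FALSE	FALSE	FALSE
PC	4.17	m	TRUE	HG_vs_LG	-3.1	1.7	8.1e-3	TRUE	TRUE	FALSE
PE	3.98	m	TRUE	PDA_vs_HG	-2.6	1.5	1.2e-3	FALSE	FALSE	FALSE
Phenylalanine	7.42	t	TRUE	LG_vs_N	2.3	1.5	2.4e-2	FALSE	FALSE	FALSE
Proline	1.99	m	TRUE	PDA_vs_HG	1.8	1.2	1.4e-2	FALSE	TRUE	FALSE
Sucrose	5.42	d	TRUE	LG_vs_N	1.9	1.4	1.8e-2	FALSE	FALSE	TRUE
Sucrose	5.42	d	TRUE	HG_vs_LG	1.8	1.4	2.1e-2	TRUE	FALSE	TRUE
Tyrosine	7.20	d	TRUE	LG_vs_N	-3.3	1.7	2.4e-4	FALSE	FALSE	FALSE
UDP-Glc/GlcA	7.95	d	TRUE	LG_vs_N	-2.9	1.6	3.3e-3	FALSE	FALSE	FALSE
UDP-Glc/GlcA	7.95	d	TRUE	HG_vs_LG	-2.1	1.4	1.8e-2	TRUE	FALSE	FALSE
UDP-Glc/GlcA	7.95	d	TRUE	Sarc_vs_PDA	1.4	1.2	1.2e-2	TRUE	FALSE	FALSE
UDP-GlcNAc	5.52	dd	TRUE	LG_vs_N	-3.6	1.9	4.2e-3	FALSE	FALSE	FALSE
UMP	8.10	d	TRUE	HG_vs_LG	-3.5	1.8	1.5e-4	FALSE	FALSE	FALSE
Valine	1.05	d	TRUE	LG_vs_N	-2.1	1.4	7.4e-3	FALSE	FALSE	FALSE
U2 d2.08	2.08	s	FALSE	LG_vs_N	-2.3	1.5	3.2e-3	FALSE	FALSE	FALSE
U3 d2.68	2.68	t	FALSE	LG_vs_N	3.3	1.7	4.9e-4	FALSE	FALSE	FALSE
U3 d2.68	2.68	t	FALSE	HG_vs_LG	-5.1	2.3	2.3e-5	FALSE	FALSE	FALSE
U4 d5.16	5.16	d	FALSE	HG_vs_LG	-2.4	1.5	1.8e-2	TRUE	FALSE	FALSE
U5 d5.56	5.56	dd	FALSE	LG_vs_N	-1.9	1.4	2.4e-2	FALSE	FALSE	FALSE
U9 d7.49	7.49	t	FALSE	LG_vs_N	4.0	2.0	1.5e-4	FALSE	FALSE	FALSE
U11 d2.59	2.59	s	FALSE	LG_vs_N	1.8	1.3	1.5e-2	FALSE	FALSE	FALSE
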