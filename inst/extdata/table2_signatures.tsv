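metabolite	ppm	multiplicity	identified	pt_signature_member	comparison	signature	es	es_error	p_value	fdr_ns	cell_maintained
3-HIVA	1.25	s	TRUE	FALSE	Pt_vs_N	cell	-1.7	1.3	1.2e-3	FALSE	TRUE
3-HIVA	1.25	s	TRUE	FALSE	Pt_vs_LG	tissue	-1.7	1.4	4.3e-3	FALSE	FALSE
ADP	8.28	s	TRUE	TRUE	Pt_vs_N	tissue	3.5	1.7	2.9e-3	FALSE	FALSE
ADP	8.28	s	TRUE	TRUE	Pt_vs_LG	tissue	3.3	1.8	4.3e-3	FALSE	TRUE
ADP	8.28	s	TRUE	TRUE	Pt_vs_LG	cell	2.2	1.5	4.3e-3	FALSE	FALSE
Alanine	1.48	d	TRUE	TRUE	Pt_vs_N	tissue	-5.8	2.5	3.9e-5	FALSE	TRUE
Alanine	1.48	d	TRUE	TRUE	Pt_vs_N	cell	-5.3	2.3	2.4e-5	FALSE	FALSE
Alanine	1.48	d	TRUE	TRUE	Pt_vs_LG	tissue	-2.1	1.5	4.0e-2	TRUE	TRUE
Alanine	1.48	d	TRUE	TRUE	Pt_vs_LG	cell	-1.8	1.4	3.2e-2	TRUE	FALSE
AMP	8.60	s	TRUE	TRUE	Pt_vs_N	tissue	-4.5	2.1	1.1e-5	FALSE	TRUE
AMP	8.60	s	TRUE	TRUE	Pt_vs_N	cell	-4.9	2.2	7.5e-6	FALSE	FALSE
AMP	8.60	s	TRUE	TRUE	Pt_vs_LG	tissue	-7.4	3.3	2.1e-6	FALSE	TRUE
AMP	8.60	s	TRUE	TRUE	Pt_vs_LG	cell	-3.2	1.8	5.1e-3	FALSE	FALSE
ATP	6.14	d	TRUE	TRUE	Pt_vs_N	tissue	5.2	2.3	2.5e-5	FALSE	FALSE
ATP	6.14	d	TRUE	TRUE	Pt_vs_LG	tissue	6.2	2.9	5.9e-6	FALSE	TRUE
ATP	6.14	d	TRUE	TRUE	Pt_vs_LG	cell	1.7	1.4	3.1e-2	TRUE	FALSE
Creatine	3.04	s	TRUE	FALSE	Pt_vs_N	tissue	-4.4	2.0	1.7e-4	FALSE	TRUE
Creatine	3.04	s	TRUE	FALSE	Pt_vs_N	cell	-3.7	1.8	3.1e-4	FALSE	FALSE
Creatinine	3.05	s	TRUE	FALSE	Pt_vs_N	cell	-2.1	1.4	4.6e-3	FALSE	TRUE
Creatinine	3.05	s	TRUE	FALSE	Pt_vs_LG	tissue	4.0	2.0	4.3e-3	FALSE	FALSE
Formate	8.46	s	TRUE	TRUE	Pt_vs_N	tissue	-3.8	1.8	1.2e-3	FALSE	FALSE
Formate	8.46	s	TRUE	TRUE	Pt_vs_N	cell	-6.6	2.8	5.7e-7	FALSE	FALSE
Formate	8.46	s	TRUE	TRUE	Pt_vs_LG	tissue	-4.3	2.1	4.3e-3	FALSE	TRUE
Formate	8.46	s	TRUE	TRUE	Pt_vs_LG	cell	-2.4	1.6	8.8e-3	TRUE	FALSE
Fumarate	6.52	s	TRUE	FALSE	Pt_vs_N	tissue	-1.7	1.3	1.5e-2	FALSE	TRUE
Fumarate	6.52	s	TRUE	FALSE	Pt_vs_N	cell	-3.8	1.8	1.3e-4	FALSE	FALSE
Fumarate	6.52	s	TRUE	FALSE	Pt_vs_LG	cell	-2.3	1.5	3.1e-2	TRUE	FALSE
Glucose	5.23	d	TRUE	FALSE	Pt_vs_N	tissue	2.2	1.3	2.2e-3	FALSE	FALSE
Glucose	5.23	d	TRUE	FALSE	Pt_vs_LG	cell	-1.9	1.4	4.9e-2	TRUE	FALSE
Glutamate	2.35	m	TRUE	FALSE	Pt_vs_N	tissue	5.1	2.3	7.2e-6	FALSE	FALSE
Glutamate	2.35	m	TRUE	FALSE	Pt_vs_N	cell	-1.6	1.2	4.8e-2	TRUE	FALSE
Glutamine	2.45	m	TRUE	FALSE	Pt_vs_N	cell	-2.5	1.5	3.6e-3	FALSE	TRUE
Glutamine	2.45	m	TRUE	FALSE	Pt_vs_LG	tissue	3.2	1.8	1.2e-3	FALSE	FALSE
GPC	3.23	s	TRUE	FALSE	Pt_vs_N	tissue	-1.4	1.2	4.3e-2	TRUE	TRUE
GPC	3.23	s	TRUE	FALSE	Pt_vs_N	cell	-2.7	1.5	1.0e-3	FALSE	FALSE
GPC	3.23	s	TRUE	FALSE	Pt_vs_LG	tissue	-2.0	1.5	4.6e-2	TRUE	TRUE
GPC	3.23	s	TRUE	FALSE	Pt_vs_LG	cell	-2.0	1.4	2.1e-2	TRUE	FALSE
GSH	4.57	m	TRUE	TRUE	Pt_vs_N	tissue	9.5	3.8	1.2e-3	FALSE	FALSE
GSH	4.57	m	TRUE	TRUE	Pt_vs_LG	tissue	12	5.3	4.3e-3	FALSE	FALSE
GSH	4.57	m	TRUE	TRUE	Pt_vs_LG	cell	1.7	1.4	3.1e-2	TRUE	FALSE
Histidine	7.08	s	TRUE	FALSE	Pt_vs_N	tissue	-2.7	1.5	9.2e-4	FALSE	TRUE
Histidine	7.08	s	TRUE	FALSE	Pt_vs_N	cell	-4.9	2.2	9.0e-5	FALSE	FALSE
Lactate	1.33	d	TRUE	FALSE	Pt_vs_N	cell	-2.0	1.3	9.3e-3	FALSE	TRUE
Lactate	1.33	d	TRUE	FALSE	Pt_vs_LG	tissue	-2.7	1.7	1.8e-2	FALSE	TRUE
Lactate	1.33	d	TRUE	FALSE	Pt_vs_LG	cell	-2.2	1.5	2.8e-2	TRUE	FALSE
Leucine	0.96	t	TRUE	FALSE	Pt_vs_N	cell	-1.7	1.3	1.8e-2	FALSE	TRUE
Leucine	0.96	t	TRUE	FALSE	Pt_vs_LG	tissue	1.9	1.4	1.9e-2	FALSE	FALSE
NAD+	9.34	s	TRUE	FALSE	Pt_vs_N	cell	-1.7	1.3	1.7e-2	FALSE	TRUE
NAD+	9.34	s	TRUE	FALSE	Pt_vs_LG	tissue	2.0	1.4	3.9e-2	TRUE	FALSE
Niacinamide	8.94	d	TRUE	TRUE	Pt_vs_N	tissue	-2.9	1.6	7.6e-4	FALSE	TRUE
Niacinamide	8.94	d	TRUE	TRUE	Pt_vs_N	cell	-3.2	1.7	5.1e-4	FALSE	FALSE
Niacinamide	8.94	d	TRUE	TRUE	Pt_vs_LG	tissue	-3.5	1.9	3.6e-3	FALSE	TRUE
Niacinamide	8.94	d	TRUE	TRUE	Pt_vs_LG	cell	-2.2	1.5	3.1e-2	TRUE	FALSE
PC	3.22	s	TRUE	FALSE	Pt_vs_N	tissue	-2.3	1.4	2.8e-3	FALSE	TRUE
PC	3.22	s	TRUE	FALSE	Pt_vs_N	cell	-3.6	1.8	1.0e-4	FALSE	FALSE
PC	3.22	s	TRUE	FALSE	Pt_vs_LG	tissue	3.8	2.0	1.7e-3	FALSE	FALSE
Phenylacetate	7.26	t	TRUE	TRUE	Pt_vs_N	tissue	3.4	1.7	2.9e-3	FALSE	FALSE
Phenylacetate	7.26	t	TRUE	TRUE	Pt_vs_LG	tissue	2.0	1.5	2.9e-2	TRUE	FALSE
Phenylalanine	7.42	t	TRUE	FALSE	Pt_vs_N	tissue	4.0	1.9	4.4e-5	FALSE	FALSE
Succinate	2.41	s	TRUE	FALSE	Pt_vs_N	cell	-2.5	1.4	1.9e-3	FALSE	TRUE
Succinate	2.41	s	TRUE	FALSE	Pt_vs_LG	tissue	-2.2	1.5	2.9e-2	TRUE	FALSE
Taurine	3.26	t	TRUE	FALSE	Pt_vs_N	tissue	2.8	1.5	1.2e-3	FALSE	FALSE
TMAO	3.27	s	TRUE	TRUE	Pt_vs_N	tissue	-2.0	1.3	8.6e-3	FALSE	TRUE
TMAO	3.27	s	TRUE	TRUE	Pt_vs_N	cell	-4.0	1.9	4.6e-5	FALSE	FALSE
TMAO	3.27	s	TRUE	TRUE	Pt_vs_LG	tissue	-1.6	1.4	4.3e-3	FALSE	FALSE
Tyrosine	7.20	d	TRUE	FALSE	Pt_vs_N	tissue	-3.4	1.7	3.7e-4	FALSE	TRUE
Tyrosine	7.20	d	TRUE	FALSE	Pt_vs_N	cell	-3.5	1.7	1.7e-4	FALSE	FALSE
UDP-Glc/GlcA	7.95	d	TRUE	FALSE	Pt_vs_N	cell	-2.7	1.5	1.5e-3	FALSE	TRUE
UDP-Glc/GlcA	7.95	d	TRUE	FALSE	Pt_vs_LG	tissue	4.1	2.1	7.4e-4	FALSE	FALSE
UDP-GlcNAc	5.52	dd	TRUE	FALSE	Pt_vs_N	tissue	-3.3	1.7	6.2e-4	FALSE	TRUE
UDP-GlcNAc	5.52	dd	TRUE	FALSE	Pt_vs_N	cell	-4.8	2.1	1.8e-5	FALSE	FALSE
UMP	8.10	d	TRUE	TRUE	Pt_vs_N	tissue	-2.1	1.4	4.5e-4	FALSE	TRUE
UMP	8.10	d	TRUE	TRUE	Pt_vs_N	cell	-3.9	1.8	6.8e-5	FALSE	FALSE
UMP	8.10	d	TRUE	TRUE	Pt_vs_LG	tissue	-3.3	1.8	3.0e-3	FALSE	TRUE
UMP	8.10	d	TRUE	TRUE	Pt_vs_LG	cell	-1.9	1.4	2.9e-2	TRUE	FALSE
Valine	1.05	d	TRUE	FALSE	Pt_vs_N	tissue	-2.0	1.3	5.9e-3	FALSE	TRUE
Valine	1.05	d	TRUE	FALSE	Pt_vs_N	cell	-3.7	1.8	5.7e-5	FALSE	FALSE
U1 d1.58	1.58	d	FALSE	FALSE	Pt_vs_N	tissue	-1.7	1.3	2.2e-2	FALSE	TRUE
U1 d1.58	1.58	d	FALSE	FALSE	Pt_vs_N	cell	-2.1	1.4	1.2e-3	FALSE	FALSE
U2 d2.08	2.08	s	FALSE	FALSE	Pt_vs_N	tissue	-2.4	1.4	4.0e-3	FALSE	TRUE
U2 d2.08	2.08	s	FALSE	FALSE	Pt_vs_N	cell	-3.2	1.7	2.1e-4	FALSE	FALSE
U3 d2.68	2.68	t	FALSE	FALSE	Pt_vs_N	tissue	3.3	1.7	1.9e-4	TRUE	FALSE
U4 d5.16	5.16	d	FALSE	FALSE	Pt_vs_N	tissue	10.4	4.1	4.8e-9	FALSE	FALSE
U4 d5.16	5.16	d	FALSE	FALSE	Pt_vs_LG	tissue	13	5.6	4.3e-3	FALSE	TRUE
U4 d5.16	5.16	d	FALSE	FALSE	Pt_vs_LG	cell	2.2	1.5	1.3e-7	FALSE	FALSE
U5 d5.56	5.56	dd	FALSE	FALSE	Pt_vs_N	cell	-4.2	1.9	6.5e-5	TRUE	FALSE
U6 d5.70	5.70	s	FALSE	FALSE	Pt_vs_N	tissue	3.1	1.6	1.3e-3	FALSE	FALSE
U6 d5.70	5.70	s	FALSE	FALSE	Pt_vs_LG	tissue	3.8	2.0	9.5e-4	FALSE	TRUE
U6 d5.70	5.70	s	FALSE	FALSE	Pt_vs_LG	cell	3.8	2.0	9.5e-4	FALSE	FALSE
U7 d6.03	6.03	d	FALSE	FALSE	Pt_vs_N	tissue	1.6	1.3	2.5e-2	FALSE	FALSE
U7 d6.03	6.03	d	FALSE	FALSE	Pt_vs_LG	tissue	7.1	3.2	5.3e-4	FALSE	FALSE
U8 d6.80	6.80	s	FALSE	FALSE	Pt_vs_N	tissue	-1.6	1.2	2.5e-2	FALSE	TRUE
U8 d6.80	6.80	s	FALSE	FALSE	Pt_vs_N	cell	-1.6	1.2	2.9e-2	FALSE	FALSE
U8 d6.80	6.80	s	FALSE	FALSE	Pt_vs_LG	tissue	3.5	1.9	6.7e-3	FALSE	TRUE
U8 d6.80	6.80	s	FALSE	FALSE	Pt_vs_LG	cell	-3.1	1.8	4.3e-3	FALSE	FALSE
U9 d7.49	7.49	t	FALSE	FALSE	Pt_vs_N	cell	-3.0	1.6	1.3e-3	TRUE	FALSE
U9 d7.49	7.49	t	FALSE	FALSE	Pt_vs_LG	tissue	-3.7	2.0	4.8e-4	TRUE	FALSE
U9 d7.49	7.49	t	FALSE	FALSE	Pt_vs_LG	cell	-2.4	1.6	1.6e-2	FALSE	FALSE
U10 d8.21	8.21	s	FALSE	FALSE	Pt_vs_N	tissue	-1.7	1.3	2.1e-2	FALSE	TRUE
U10 d8.21	8.21	s	FALSE	FALSE	Pt_vs_N	cell	-2.8	1.5	1.3e-3	FALSE	FALSE
U10 d8.21	8.21	s	FALSE	FALSE	Pt_vs_LG	tissue	-2.4	1.6	3.1e-2	TRUE	FALSE
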