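group	condition	n	strain	age_months	avg_cell_count	cell_count_rel_error
N	Control	7	C57BL/6 (WT)	1.5-2	1761	0.19
Pt	Pancreatitis	6	C57BL/6 (WT)	1.5-2	4454	0.08
LG	Low-grade PanIN lesions	5	LSL-KrasG12D/+ - p48Cre/+	2-4	2794	0.19
HG	High-grade PanIN lesions	7	LSL-KrasG12D/+ - p48Cre/+	9	2422	0.07
PDA	Pancreatic ductal adenocarcinoma	6	LSL-KrasG12D/+;LSL-Trp53R172H/+;Pdx-1-Cre	3-6	2318	0.29
Sarc	Sarcomatoid carcinoma	9	LSL-KrasG12D/+;LSL-Trp53R172H/+;Pdx-1-Cre	3-6	2958	0.19
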