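locus	gene	kind	label	position	freq_case	freq_control	or	reference
HLA-C	HLA-C	allele	C*06:02	NA	0.23	0.093	3.26	FALSE
HLA-C	HLA-C	allele	C*12:03	NA	0.073	0.056	1.38	FALSE
HLA-C	HLA-C	allele	other	NA	0.70	0.85	NA	TRUE
HLA-B position 67	HLA-B	residue	C	67	0.16	0.12	1.56	FALSE
HLA-B position 67	HLA-B	residue	M	67	0.12	0.046	1.44	FALSE
HLA-B position 67	HLA-B	residue	Y	67	0.12	0.16	1.00	FALSE
HLA-B position 67	HLA-B	residue	F	67	0.21	0.26	1.00	FALSE
HLA-B position 67	HLA-B	residue	S	67	0.39	0.42	NA	TRUE
HLA-B position 9	HLA-B	residue	D	9	0.096	0.11	1.33	FALSE
HLA-B position 9	HLA-B	residue	Y	9	0.70	0.67	NA	TRUE
HLA-B position 9	HLA-B	residue	H	9	0.20	0.22	0.87	FALSE
HLA-A position 95	HLA-A	residue	V	95	0.34	0.29	1.31	FALSE
HLA-A position 95	HLA-A	residue	I	95	0.56	0.59	NA	TRUE
HLA-A position 95	HLA-A	residue	L	95	0.099	0.12	0.89	FALSE
HLA-DQA1 position 53	HLA-DQA1	residue	R	53	0.37	0.29	1.07	FALSE
HLA-DQA1 position 53	HLA-DQA1	residue	K	53	0.39	0.43	NA	TRUE
HLA-DQA1 position 53	HLA-DQA1	residue	Q	53	0.25	0.29	0.91	FALSE
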