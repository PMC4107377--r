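locus_id	gene	effect_allele	other_allele	or	apoe	freq_nhw	freq_nhb
rs429358	APOE	C	T	3.685	TRUE	0.285	0.415
rs7412	APOE	T	C	0.62	TRUE	0.078	0.105
rs744373	BIN1	G	A	1.17	FALSE	0.29	0.22
rs11136000	CLU	T	C	0.88	FALSE	0.38	0.45
rs3764650	ABCA7	G	T	1.23	FALSE	0.10	0.15
rs3818361	CR1	A	G	1.17	FALSE	0.20	0.24
rs3851179	PICALM	T	C	0.88	FALSE	0.35	0.28
rs610932	MS4A6A	T	G	0.90	FALSE	0.42	0.38
rs3865444	CD33	A	C	0.89	FALSE	0.30	0.21
rs670139	MS4A4E	T	G	1.08	FALSE	0.41	0.37
rs9349407	CD2AP	C	A	1.12	FALSE	0.27	0.33
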