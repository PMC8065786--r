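measure	type	a1	a2	b1	b2	n_a	n_b	printed_p
Age	t	33.42	5.62	27.23	8.21	21	23	0.081
Gender, M/F	chisq	16	5	14	9	21	23	0.276
Handedness, LQ	t	92.45	3.65	90.28	8.25	21	23	0.269
Years of education	t	19.5	2.7	16.21	6.28	21	23	0.079
Mathematics test	t	70.95	7.13	40.71	7.69	21	23	<0.001
Intelligence test	t	115.91	12.35	124.27	15.23	21	23	0.072
WM (forward)	t	8.9	3.12	9.12	4.2	21	23	0.319
WM (backward)	t	7.3	1.9	7.62	1.59	21	23	0.273
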