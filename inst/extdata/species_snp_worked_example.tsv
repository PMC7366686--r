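region	position	A. tuberculatus (24)	A. arenicola (2)	A. palmeri (17)	A. spinosus (8)	A. dubius (1)	A. hybridus (2)
ALS-CAD	351	T	A	A	A	A	A
ALS-CAD	363	C	C	C	C	Y	T
ALS-CAD	465	T	C	C	C	C	C
ALS-CAD	495	G/S1	A/R	A/R5	A	A	A
ALS-CAD	513	T	T/C	T/C3/Y8	T	T	T
ALS-CAD	516	C	T	T	T	T	T
ALS-CAD	520	T	C	C	C	C	C
ALS-CAD	531	A	A/R	A/R7/G2	A	A	A
ALS-CAD	549	G	G	G/T1/K2	G	K	T
ALS-CAD	552	T	T/Y	T/C3/Y6	T	T	T
ALS-CAD	574	C/M2	Y/M	C/Y2/M1	C	C	C
ALS-CAD	575	C	C/Y	C	C	C	C
ALS-CAD	576	T	C	C	C	C	C
ALS-CAD	579	G/A3/R3	G	G	G	G	G
ALS-CAD	603	T	T/Y	T/C3/Y6	T	T	T
ALS-CAD	615	T	A	A	A	A	A
ALS-CAD	636	A	C	C	C	C	C
ALS-CAD	642	T	T	T/C1/Y1	T	Y	C
ALS-CAD	678	C	T	T	T	T	T
ALS-BE	1435	A	A	G	G	G	G
ALS-BE	1482	C8/T4/Y12	T	C	C	C	C
ALS-BE	1503	C23/M1	C	C/T1/Y1	C5/T4	C	C
ALS-BE	1551	A	A	A14/W3	A4/T5	W	A
ALS-BE	1554	C	C	T16/Y1	T	T	T
ALS-BE	1587	G17/A1/R6	R	G16/R1	G	G	G
ALS-BE	1602	T23/Y1	T	T15/Y2	C5/T4	T	T
ALS-BE	1611	T6/C7/Y11	Y	T	T	T	T
ALS-BE	1656	G/R6	R	G	G	R	A
ALS-BE	1770	T6/A11/W7	W	T	T	T	T
ALS-BE	1776	T11/W8/A5	W	T	T	T	T
ALS-BE	1782	C11/M8/A5	M	C	C	C	C
ALS-BE	1794	G20/A3/R2	G	G	G	G	G
ALS-BE	1809	T	T	C13/Y4	C	T	T
ALS-BE	1836	C	C	T14/Y2/C1	T	C	C
ALS-BE	1899	A	A	G	G	R	G
ALS-BE	1955	G19/R4/C1	R	G	G	G	G
ALS-BE	1956	C17/Y5/S1/T1	Y	C16/T1	C	C	C
ALS-BE	1974	C18/T1/Y5	Y	C15/Y2	C	C	C
ALS-BE	1980	C	C	C	C	M	A
ALS-BE	1983	A	A	A12/T4/W1	A	A	A
ALS-BE	2016	T	T	T11/C5/Y1	T	C	T
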