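sample_id	species	origin	codon122	codon197	codon574	codon653
120914_7_pop7	A. palmeri	Beijing	GCA	CCC	TKG	AGC
7229	A. palmeri	Beijing	GCA	CCC	TTG	AGC
120914_11_pop8	A. palmeri	Beijing	GCA	YCC	TGG	AGC
120914_12_pop8	A. palmeri	Beijing	GCA	YCC	TGG	AGC
120914_16_pop10	A. palmeri	Beijing	GCA	YCC	TGG	AGC
19	A. palmeri	Guangxi	GCA	CCC	TKG	AGC
180910	A. palmeri	Hebei	GCA	YCC	TGG	AGC
12167	A. palmeri	Jiangsu	GCA	MCC	TGG	AGC
11963	A. tuberculatus	Fujian	GCT	CCT	TKG	AGY
12010	A. tuberculatus	Fujian	AAT	CCT	TGG	AGC
12008	A. tuberculatus	Fujian	RMT	CCT	TKG	AGC
12011	A. tuberculatus	Fujian	AAT	CCT	TGG	AGC
12012	A. tuberculatus	Fujian	GCT	CCT	TKG	AGT
12015	A. tuberculatus	Fujian	AAT	CCT	TGG	AGC
09-014	A. tuberculatus	Fujian	GCT	MCT	TGG	AGC
12022	A. tuberculatus	Fujian	RMT	CCT	TKG	AGC
6	A. tuberculatus	Jiangsu	GCT	CCT	TGG	ARS
12194	A. tuberculatus	Jiangsu	GCT	CCT	TKG	ARY
12165	A. tuberculatus	Jiangsu	GCT	MCT	TKG	AGC
2012009	A. tuberculatus	Jiangsu	GCT	CCT	TGG	ACC
2012021	A. tuberculatus	Jiangsu	GCT	CCT	TGG	ARC
12571	A. tuberculatus	Shandong	GCT	CCT	TTG	AGC
12575	A. tuberculatus	Shandong	GCT	CCT	TKG	ARC
12576	A. tuberculatus	Shandong	GCT	CCT	TKG	AGC
HB	A. arenicola	Hebei	GCA	MYC	TGG	ASY
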