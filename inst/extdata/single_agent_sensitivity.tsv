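# Reported 24-hour single-agent dose-response summaries for the twelve
# antisense morpholino oligomers in HEK293 control cells and the two
# Ewing's sarcoma lines TC-32 and CHLA-10: efficacy (EC50, uM) and
# sensitivity (slope of the percent-dead-cells vs dose-in-nM regression,
# with its r^2).
target	cell_line	ec50_uM	slope_pct_per_nM	r2
XAGE1E	HEK293	0.73	0.068	0.88
CCND1	HEK293	0.49	0.101	0.87
RBM11	HEK293	0.65	0.076	0.83
CYP4F22-1	HEK293	0.51	0.098	0.76
CYP4F22-2	HEK293	0.45	0.109	0.95
CYP4F22-3	HEK293	0.50	0.099	0.98
PHGDH-1	HEK293	1.31	0.038	0.70
PHGDH-2	HEK293	1.84	0.027	0.79
IGFBP2-1	HEK293	9.98	0.005	0.04
IGFBP2-2	HEK293	1.85	-0.027	0.93
IGFBP2-3	HEK293	16.6	-0.003	0.04
IGFBP2-4	HEK293	1.85	-0.027	0.93
XAGE1E	TC-32	0.65	0.076	0.92
CCND1	TC-32	0.74	0.067	0.96
RBM11	TC-32	0.85	0.059	0.90
CYP4F22-1	TC-32	0.67	0.074	0.92
CYP4F22-2	TC-32	0.57	0.087	0.99
CYP4F22-3	TC-32	0.49	0.100	0.94
PHGDH-1	TC-32	0.66	0.075	0.95
PHGDH-2	TC-32	0.75	0.067	0.91
IGFBP2-1	TC-32	0.62	0.080	0.91
IGFBP2-2	TC-32	0.41	0.120	0.92
IGFBP2-3	TC-32	0.88	0.056	0.96
IGFBP2-4	TC-32	0.67	0.074	0.98
XAGE1E	CHLA-10	0.12	0.408	1.00
CCND1	CHLA-10	0.16	0.312	0.99
RBM11	CHLA-10	0.14	0.364	1.00
CYP4F22-1	CHLA-10	0.34	0.145	1.00
CYP4F22-2	CHLA-10	0.35	0.144	0.88
CYP4F22-3	CHLA-10	0.56	0.090	0.74
PHGDH-1	CHLA-10	0.11	0.464	0.99
PHGDH-2	CHLA-10	0.36	0.137	0.81
IGFBP2-1	CHLA-10	0.29	0.170	0.61
IGFBP2-2	CHLA-10	0.27	0.185	0.91
IGFBP2-3	CHLA-10	0.12	0.405	0.81
IGFBP2-4	CHLA-10	0.21	0.235	0.79
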