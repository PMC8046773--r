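outcome	rsid	gene	effect	ci_low	ci_high
risk	rs11125529	ACYP2	0.99	0.86	1.16
risk	rs6772228	PXK	0.81	0.62	1.07
risk	rs10936599	TERC	0.79	0.70	0.90
risk	rs7675998	NAF1	0.94	0.83	1.06
risk	rs2736100	TERT	1.07	0.96	1.18
risk	rs9420907	OBFC1	1.17	1.03	1.35
risk	rs3027234	CTC1	0.89	0.79	1.00
risk	rs8105767	ZNF208	1.14	1.02	1.27
risk	rs412658	ZNF676	1.01	0.91	1.12
risk	rs6028466	DHX35	1.23	1.08	1.50
risk	rs755017	ZBTB46	1.10	0.93	1.29
survival	rs11125529	ACYP2	0.90	0.71	1.13
survival	rs6772228	PXK	1.30	0.89	1.89
survival	rs10936599	TERC	1.20	1.00	1.43
survival	rs7675998	NAF1	1.18	0.98	1.42
survival	rs2736100	TERT	1.05	0.89	1.22
survival	rs9420907	OBFC1	0.96	0.78	1.17
survival	rs3027234	CTC1	1.03	0.86	1.23
survival	rs8105767	ZNF208	1.01	0.85	1.19
survival	rs412658	ZNF676	0.98	0.83	1.15
survival	rs6028466	DHX35	1.15	0.86	1.52
survival	rs755017	ZBTB46	0.86	0.67	1.09
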