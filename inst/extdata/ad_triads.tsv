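cpg_id	chrom	pos	meth_panel	or_meth	r_meth_expr	expr_panel	or_expr	gene
cg09070378	1	161183762	FHS	1.10	-0.10	BIOS	0.85	NDUFS2
cg07356342	1	161183820	BIOS	1.10	-0.07	BIOS	0.85	NDUFS2
cg07356342	1	161183820	FHS	1.19	-0.07	BIOS	0.85	NDUFS2
cg05659526	1	161184528	BIOS	1.14	-0.13	UTMOST	0.80	FCER1G
cg15595502	1	224564870	FHS	1.04	-0.17	UTMOST	0.91	CNIH4
cg08563189	2	127780654	FHS	1.40	0.07	BIOS	1.28	BIN1
cg19153828	2	127782651	FHS	1.06	0.09	BIOS	1.28	BIN1
cg19590598	2	127782813	FHS	1.05	0.10	BIOS	1.28	BIN1
cg22376361	2	127815133	FHS	1.60	0.10	BIOS	1.28	BIN1
cg00436254	2	127862614	FHS	1.10	0.13	BIOS	1.28	BIN1
cg17763743	3	9343967	BIOS	0.97	-0.12	BIOS	1.10	THUMPD3
cg06284479	3	37173546	FHS	1.09	-0.11	BIOS	0.89	LRRFIP2
cg15934958	3	37212084	BIOS	1.04	-0.12	BIOS	0.89	LRRFIP2
cg23963071	6	2901712	BIOS	1.02	-0.24	BIOS	0.91	SERPINB9
cg02130027	6	47444894	FHS	1.15	0.15	UTMOST	1.94	CD2AP
cg20196966	6	47445060	FHS	1.25	0.12	UTMOST	1.94	CD2AP
cg20172563	6	47487173	FHS	1.10	0.23	UTMOST	1.94	CD2AP
cg06189038	7	99767134	BIOS	1.13	-0.10	UTMOST	0.01	GAL3ST4
cg11291798	7	143103859	FHS	1.13	-0.08	BIOS	0.83	EPHA1
cg14709253	8	17519419	BIOS	0.97	0.19	UTMOST	0.76	MTUS1
cg12548824	8	17554892	FHS	1.03	-0.29	UTMOST	0.76	MTUS1
cg01993952	8	17554904	FHS	1.04	-0.20	UTMOST	0.76	MTUS1
cg22099723	8	27348453	FHS	1.11	0.08	BIOS	1.14	EPHX2
cg21666367	8	27450279	BIOS	1.06	0.11	UTMOST	1.12	EPHX2
cg24794833	8	27450748	FHS	0.81	-0.10	UTMOST	1.12	EPHX2
cg26343298	8	95960752	FHS	1.08	-0.15	UTMOST	0.69	TP53INP1
cg16915659	10	60032665	BIOS	1.05	0.16	BIOS	1.06	CISD1
cg15320596	10	61604738	BIOS	0.97	0.10	BIOS	0.60	CCDC6
cg23858360	10	82213490	BIOS	0.94	0.08	UTMOST	0.76	TSPAN14
cg16178415	10	82265445	FHS	1.09	-0.13	UTMOST	0.76	TSPAN14
cg24590430	10	99097076	BIOS	1.02	-0.10	BIOS	0.91	FRAT2
cg00091760	10	124131072	BIOS	0.83	-0.10	UTMOST	1.12	PLEKHA1
cg04353769	11	59951557	BIOS	0.69	-0.10	BIOS	1.65	MS4A6A
cg06881914	11	59951663	FHS	0.86	-0.19	BIOS	1.65	MS4A6A
cg04422903	11	64108550	FHS	1.03	-0.10	UTMOST	0.88	CCDC88B
cg01120308	11	85780971	BIOS	0.87	-0.14	BIOS	1.11	CHRNE
cg11107966	14	92927875	FHS	1.05	-0.12	BIOS	0.92	SLC24A4
cg14021523	14	92959873	FHS	1.13	-0.14	BIOS	0.92	SLC24A4
cg05200313	14	92960827	BIOS	1.14	-0.16	BIOS	0.92	SLC24A4
cg25647583	15	91427184	BIOS	0.93	-0.26	UTMOST	1.19	FES
cg05676562	16	30102457	FHS	1.11	-0.08	BIOS	0.94	TBX6
cg26709300	16	30106682	BIOS	0.95	0.10	BIOS	0.82	YPEL3
cg02335376	16	30124880	BIOS	0.90	-0.15	UTMOST	1.07	MAPK3
cg08464513	16	30136024	FHS	0.88	-0.11	UTMOST	1.07	MAPK3
cg00249205	16	31012263	FHS	0.94	0.15	UTMOST	0.81	TMEM106B
cg06233904	16	31044135	BIOS	1.10	-0.08	BIOS	0.87	STX4
cg07404961	16	31049270	FHS	0.85	0.09	BIOS	0.87	STX4
cg19048010	17	28084996	FHS	1.07	0.16	UTMOST	1.28	SSH2
cg00685795	17	40713781	FHS	1.12	0.10	BIOS	1.44	COASY
cg04266202	17	56352895	FHS	1.16	-0.19	BIOS	0.85	MPO
cg11015549	19	1026207	FHS	0.81	-0.19	UTMOST	1.11	CNN2
cg04401876	19	45445449	BIOS	1.12	0.08	UTMOST	1.12	EPHX2
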