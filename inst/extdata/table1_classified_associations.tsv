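class	SRF	DCM	MES	BAT	SRF_pct	DCM_pct	MES_pct	BAT_pct
global	26	23	21	0	0.14	0.31	0.20	NA
prevalent	22	47	10	7	0.12	0.64	0.10	0.07
low_frequency	105	160	212	51	0.58	2.17	2.05	0.51
global_no_ms	86	52	28	9	0.47	0.70	0.27	0.09
prevalent_no_ms	207	76	27	28	1.14	1.03	0.26	0.28
low_frequency_no_ms	1361	219	342	489	7.46	2.97	3.30	4.84
regional	2014	2290	3420	3669	11.05	31.03	33.00	36.33
regional_MS	596	1295	2254	1217	3.27	17.55	21.75	12.05
regional_NAO	577	306	422	1522	3.16	4.15	4.07	15.07
regional_SAO	162	304	301	143	0.89	4.12	2.90	1.42
regional_SPO	152	105	40	109	0.83	1.42	0.39	1.08
regional_NPO	298	133	204	516	1.63	1.80	1.97	5.11
regional_IO	229	147	199	162	1.26	1.99	1.92	1.60
other	16067	4860	6701	6372	88.12	65.85	64.66	63.10
other_no_ms	14566	4743	6547	55904	79.88	64.27	62.17	58.46
present	18234	7380	10364	10099	100	100	100	100
absent	10884	21738	18754	19019	NA	NA	NA	NA
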