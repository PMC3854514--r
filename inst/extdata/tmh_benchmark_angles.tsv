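# Rotational-angle benchmark: 73 transmembrane helices from 14 polytopic
# membrane protein chains (the Harrington & Ben-Tal helix-packing set).
# observed  = rotational angle from the solved structure (degrees, [0,360));
# predicted = rASA-moment rotational angle from sequence (degrees, [0,360));
# error     = published absolute angular error (degrees);
# chain_maae = published per-chain mean absolute angular error (degrees);
# moment_length = published rASA moment length.
chain	helix	sequence	observed	predicted	error	moment_length	chain_maae
1BL8:A	1	HWRAAGAATVLLVIVLLAGSYLAVLA	199.55	203.38	3.83	1.46	30.86
1BL8:A	2	WGRCVAVVVMVAGITSFGLVTAALAT	240.88	298.78	57.90	1.87	30.86
1C3W:A	1	IWLALGTALMGLGTLYFLVKGMG	318.98	355.18	36.19	3.38	42.28
1C3W:A	2	KFYAITTLVPAIAFTMYLSMLL	262.69	313.32	50.63	2.74	42.28
1C3W:A	3	WARYADWLFTTPLLLLDLALL	118.84	44.89	73.95	1.60	42.28
1C3W:A	4	GTILALVGADGIMIGTGLVGAL	357.99	332.94	25.05	2.80	42.28
1C3W:A	5	RFVWWAISTAAMLYILYVLFFGF	154.03	169.74	15.71	2.25	42.28
1C3W:A	6	FKVLRNVTVVLWSAYPVVWLIG	133.56	164.23	30.67	2.70	42.28
1C3W:A	7	ETLLFMVLDVSAKVGFGLILLRS	214.98	278.73	63.75	1.93	42.28
1OKC:A	1	LSFLKDFLAGGVAAAISKTAVAPIER	24.46	46.33	21.87	1.59	65.78
1OKC:A	2	NLANVIRYFPTQALNFAFKDKYKQIFL	207.77	114.64	93.14	1.75	65.78
1OKC:A	3	WRYFAGNLASGGAAGATSLCFVYPLDFART	112.40	70.30	42.09	1.32	65.78
1OKC:A	4	YQGFNVSVQGIIIYRAAYFGVYDTAKGMLP	179.94	59.44	120.50	1.40	65.78
1OKC:A	5	HIIVSWMIAQTVTAVAGLVSYPFDTVRR	264.34	315.20	50.85	0.98	65.78
1OKC:A	6	AWSNVLRGMGGAFVLVLYDEI	172.16	105.90	66.25	1.87	65.78
1ORS:C	1	VELGVSYAALLSVIVVVVEYTMQL	268.82	191.51	77.31	0.70	62.09
1ORS:C	2	LVRLYLVDLILVIILWADYAY	167.76	133.29	34.46	1.71	62.09
1ORS:C	3	KKTLYEIPALVPAGLLALIE	27.58	321.07	66.51	0.72	62.09
1ORS:C	4	LVRLLRFLRILLIISRGSKFLSAIA	233.80	303.87	70.07	0.62	62.09
2B6O:A	1	RAIFAEFFATLFYVFFGLGAS	308.42	335.32	26.90	1.44	33.01
2B6O:A	2	LQVALAFGLALATLVQAVGHIS	59.48	65.56	6.07	1.17	33.01
2B6O:A	3	LRAICYVVAQLLGAVAGAAVLYSV	354.70	13.71	19.01	2.35	33.01
2B6O:A	4	GQATIVEIFLTLQFVLCIFATY	61.06	71.11	10.05	1.58	33.01
2B6O:A	5	GSVALAVGFSLTLGHLFGM	342.15	109.29	127.14	1.21	33.01
2B6O:A	6	WVYWVGPVIGAGLGSLLYDFLL	49.77	58.65	8.88	1.58	33.01
2BL2:A	1	VLAMATATIFSGIGSAKGVG	45.15	105.31	60.16	0.99	41.83
2BL2:A	2	LPGTQGLYGFVIAFLIFI	285.84	259.80	26.04	1.70	41.83
2BL2:A	3	LGASLPIAFTGLFSGIAQ	82.57	87.25	4.68	1.39	41.83
2BL2:A	4	MVETYAILGFVISFLLVL	7.10	290.64	76.46	1.13	41.83
2BS2:C	1	WQSATGLFLGLFMIGHMFFVST	285.17	308.25	23.08	1.79	51.33
2BS2:C	2	IVVSFLAAFVFAVFIAHAFLAMR	55.33	17.57	37.76	2.89	51.33
2BS2:C	3	LWWIQAMTGFAMFFLGSVHLYIMMTQP	188.56	222.27	33.71	1.48	51.33
2BS2:C	4	WMWPLYLVLLFAVELHGSVGLYRLAV	192.12	322.45	130.33	1.38	51.33
2BS2:C	5	RANLKKLKTLMSAFLIVLGLLTFGAYV	185.58	153.82	31.76	3.30	51.33
2H88:C	1	HRGTGVALSLGVSLFSLAALLLP	123.28	203.88	80.60	1.69	45.70
2H88:C	2	LIYSAKFALVFPLSYHTWNGIR	307.08	253.07	54.01	0.39	45.70
2H88:C	3	VVVLILTLLSSAAIASE	74.04	71.55	2.50	2.05	45.70
2H88:D	1	VSALLLGLLPAAYLYPG	229.60	234.10	4.50	1.06	27.22
2H88:D	2	AVDYSLAAALTLHGHWGL	8.24	354.67	13.57	0.95	27.22
2H88:D	3	GLYVLSAITFTGLCYFNYYDV	334.89	271.30	63.59	1.49	27.22
2OAR:A	1	VAVVIGTAFTALVTKFTDSIITPLINRIG	319.36	203.39	115.96	0.37	113.71
2OAR:A	2	TIDLNVLLSAAINFFLIAFAVYFL	105.75	354.30	111.46	1.06	113.71
2QTS:A	1	VWALCFMGSLALLALVCTNRIQ	285.04	280.66	4.38	2.32	11.07
2QTS:A	2	AGLLGDIGGQMGLFIGASILTVL	41.15	23.39	17.76	2.22	11.07
2RH1:A	1	WVVGMGIVMSLIVLAIVFGNVLVITAIA	253.60	259.99	6.39	1.71	35.73
2RH1:A	2	YFITSLACADLVMGLAVVPFGAAHIL	293.99	341.90	47.91	1.06	35.73
2RH1:A	3	WCEFWTSIDVLCVTASIETLCVIAV	279.34	285.10	5.77	0.68	35.73
2RH1:A	4	RVIILMVWIVSGLTSFLPIQMHWYR	88.76	102.09	13.33	1.93	35.73
2RH1:A	5	FTNQAYAIASSIVSFYVPLVIMVFVYS	158.19	84.71	73.47	1.88	35.73
2RH1:A	6	LGIIMGTFTLCWLPFFIVNIVHVIQ	106.50	159.31	52.82	1.40	35.73
2RH1:A	7	IRKEVYILLNWIGYVNSGFNPLIYC	271.42	321.81	50.39	1.50	35.73
2UUH:A	1	AAVTLLGVLLQAYF	60.17	77.84	17.67	1.38	10.47
2UUH:A	2	SEYFPLFLATLWVAG	96.55	80.38	16.17	0.77	10.47
2UUH:A	3	AALCGLVYLFARLR	191.79	197.96	6.17	2.39	10.47
2UUH:A	4	LYASARALWLLVALAAL	116.59	118.45	1.86	2.57	10.47
2Z73:A	1	SLGIFIGICGIIGCGGNGIVIY	276.78	317.73	40.94	3.01	35.30
2Z73:A	2	FIINLAFSDFTFSLVNGFPLMTI	206.68	252.82	46.14	1.12	35.30
2Z73:A	3	VYGFIGGIFGFMSIMTMAMISI	303.09	339.23	36.14	0.80	35.30
2Z73:A	4	FIMIIFVWLWSVLWAIGPIF	99.36	72.24	27.11	2.67	35.30
2Z73:A	5	NILCMFILGFFGPILIIFFCYF	270.54	293.89	23.35	2.49	35.30
2Z73:A	6	SIVIVSQFLLSWSPYAVVAL	127.57	154.75	27.18	2.12	35.30
2Z73:A	7	QLPVMFAKASAIHNPMIYSV	60.63	106.85	46.22	2.01	35.30
3B9W:A	1	YSINILAMLLVGFGFLMV	232.00	229.10	2.90	0.63	33.25
3B9W:A	2	ATTGTYLVVATGLPLYILL	193.50	227.23	33.73	0.87	33.25
3B9W:A	3	IYAEFAVATGLIAMGAVL	221.13	199.82	21.31	0.05	33.25
3B9W:A	4	FQYALLALFIVPVYLLNE	11.39	35.81	24.42	1.15	33.25
3B9W:A	5	GSIAIHAFGAYFGLGVSIA	208.92	309.21	100.29	0.73	33.25
3B9W:A	6	FSMLGSMVLWLFWPSFA	284.14	287.41	3.27	1.16	33.25
3B9W:A	7	VNTLLALCGATLATYFLSAL	36.54	3.47	33.07	1.57	33.25
3B9W:A	8	VDMANAALAGGVAIGSVC	138.00	55.95	82.05	0.24	33.25
3B9W:A	9	VGAFVIGLLGGAISVVGF	11.05	21.65	10.60	1.90	33.25
3B9W:A	10	TCGVHNLHGLPGLLGGFSAIL	112.57	156.18	43.61	0.92	33.25
3B9W:A	11	LTGIGITLALALIGGVIAGALIKLT	103.20	92.65	10.55	2.58	33.25
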