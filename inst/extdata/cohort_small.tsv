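patient_id	group	sex	age	osdi_symptoms	osdi_vision	osdi_triggers	osdi_total	oxford	pain	schirmer_mm	tbut_s	mean_ic_density	mean_nfd	mean_tortuosity	mean_reflectivity	hla_dr_auf	mean_nfl	ic_sub	ic_code	nd_sub	nd_code	nm_sub	nm_code	tivcm
P0001	AIDED	F	56.6048075269784	9.60388966296219	12.4537657897946	9.59950044700105	68.4909896106132	0	8	18.6355266191472	9.03592310976035	47.3904926626947	8.74069200313984	1.28966362464072	3.55481522243568	123678.801931479	2.42017031948672	1	IC-1	1	ND-2	2	NM-2	4
P0002	AIDED	F	57.7008318607507	10.4053793999435	11.1403003948343	3.59227041207651	51.2379875245271	2	7	1.11704675626947	1.09675172219375	74.4666112210278	21.6124279310654	1.22577017689823	6.06318067667449	33586.8206236971	5.22141288137422	2	IC-2	0	ND-1	2	NM-2	4
P0003	AIDED	F	61.532204857511	6.81935418189707	1.9188898950744	5.52693264445688	25.325738708533	1	2	19.5379495667862	2.68916215537891	71.9042539860945	16.8889879011496	1.38953517887456	4.96042992063353	84129.1478863415	4.426428046151	2	IC-2	0	ND-1	2	NM-2	4
P0004	AIDED	F	53.6969128252637	11.6325827082901	3.82999089281072	6.58799019761437	47.9443181569451	3	4	2.580308304727	5.32844996888635	87.0981755997015	10.3528355442211	1.52204021119765	2.59165692519329	167173.364444213	2.46049955256128	2	IC-2	1	ND-2	2	NM-2	5
P0005	AIDED	F	41.6419169873367	13.3351811354943	6.73961686583198	12.3552723676001	73.7368750104894	3	7	31.3142541067435	6.92197944530058	48.7368325636616	26.6157764808142	1.19800679757785	4.13283021511856	114767.276752196	5.64675491220322	1	IC-1	0	ND-1	1	NM1-R	2
P0006	AIDED	F	40.735323665231	13.7229829713886	7.53386242683995	11.6666598561068	79.6727976220588	1	3	12.3118961466352	3.14304615929067	79.4015020596958	26.1583478651574	1.0840565305876	4.31780582999402	167270.626062427	8.26699566080479	2	IC-2	0	ND-1	1	NM1-R	3
P0007	NAIDED	M	89.3350223150257	8.34409267378904	1.87989333936651	6.16418694761263	14.5427552554182	0	6	34.5663687266708	7.67366119875628	98.3625562498112	21.7883215724122	1.28833781781992	7.44895512379463	36300.2507043634	6.10602788247554	2	IC-2	0	ND-1	2	NM-2	4
P0008	NAIDED	F	71.0263884513896	7.58828814887066	13.4880179257061	7.12614751389903	61.2422310515923	1	5	3.05290763708602	9.12029877251469	95.930102308093	46.3551684950253	1.19536850556744	3.80243619830086	27483.8541610988	12.8319136122097	2	IC-2	0	ND-1	1	NM1-R	3
P0009	NAIDED	F	30.3149173314168	15.9154485718636	17.3280195012644	15.1091680832843	91.9876272741208	0	1	10.4412818841411	9.63096453818282	73.0416051116341	11.9608257584853	1.09869127812141	3.56237990803747	71665.2382399037	3.50508121467206	2	IC-2	1	ND-2	1	NM1-R	4
P0010	NAIDED	M	55.8516317310808	15.5405702267499	2.87568594601563	3.82060785249803	52.8084493152014	0	1	10.8874029907885	7.89547895778935	62.579201860668	13.2739440592369	1.46200925743225	2.46102511166297	25707.2314850017	3.13930476218074	2	IC-2	1	ND-2	1	NM1-T	4
P0011	NAIDED	F	70.9562427309423	11.8747620488792	10.0271748516103	9.84191313461639	70.3289690580318	0	6	34.6599772455816	12.0508598246427	70.5828105969166	19.5500396124034	1.39095011891376	6.36585439132634	211815.038323688	5.23532855345879	2	IC-2	0	ND-1	2	NM-2	4
P0012	NAIDED	F	77.0076298595964	5.23119552823214	4.31897049370482	0.501367979766623	25.6206066616779	1	1	29.3924010122772	15.2865431097404	22.2117366827699	8.4523942726568	1.22818744771128	9.57509559402988	44194.007399571	3.27745409625412	1	IC-1	1	ND-2	2	NM-2	4
P0013	NAIDED	F	52.5737869241476	18.2444366026516	2.11721872460197	7.16416253834411	64.3954629800694	0	3	24.7302188372923	7.169077149554	51.8809500757573	24.971903610255	1.12851218996707	2.43827695018466	151291.726076595	8.93156596716548	2	IC-2	0	ND-1	0	NM-0	2
P0014	NAIDED	F	79.72377782589	7.0533081439534	15.9350210447338	4.49918835304203	62.6068418991922	3	2	1.00796315653342	3.66495660985435	107.28008646737	15.2212865873126	1.47411053137726	4.77789544579445	255839.547351058	5.8643728935777	3	IC-3	0	ND-1	2	NM-2	5
P0015	NAIDED	F	34.3099787288995	0.62296466487631	0.0583052322683377	1.57557365180839	13.8014926922672	0	2	31.5245304145407	5.85893509779449	16.6829947887657	36.2265182945997	1.11534668216745	4.38495943748119	81885.0881647408	10.0045116755618	1	IC-1	0	ND-1	1	NM1-R	2
P0016	NAIDED	F	37.1455572816287	10.3359545081182	3.8602546717239	9.79444971833392	51.2247345466514	2	7	19.9054448312727	5.01239540211371	101.445775474634	36.7088967824233	1.50033738748139	7.29171517560939	109224.568407699	11.8599704228448	3	IC-3	0	ND-1	2	NM-2	5
P0017	NAIDED	M	52.6356680407368	19.4012880744874	10.7323310556021	6.86621156861133	71.5773217042791	0	8	27.1867682855212	5.16354971582286	84.3274167151342	12.1120609206122	1.26162494679698	5.05612940624398	21822.6374497348	3.39162102994309	2	IC-2	1	ND-2	2	NM-2	5
P0018	NAIDED	F	54.9333109467796	2.42453885004324	8.83372056092224	4.97688217863976	42.7163471958668	1	5	4.57368830561592	1.67598025213057	20.3926769582803	10.862526242652	1.31445398678078	3.39475759422618	13229.561538713	4.36214740665204	1	IC-1	1	ND-2	2	NM-2	4
P0019	NAIDED	M	48.6748699308979	18.0729617807442	4.49646400609201	12.3795154790376	59.6224894400793	0	9	34.7855840728608	6.96241561744957	61.1041125343265	11.2218793980875	2.09538401205361	5.24594514603814	103470.17094362	3.20128843590192	2	IC-2	1	ND-2	2	NM-2	5
P0020	NAIDED	F	74.8154525133571	5.02848055017385	6.86171962421992	4.32581635304298	56.4152996600163	2	6	16.7915766249664	5.14766142380605	24.3283054396404	15.1022135575662	1.41987990040694	4.76855408041548	28501.2737574872	4.17881813604297	1	IC-1	0	ND-1	2	NM-2	3
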