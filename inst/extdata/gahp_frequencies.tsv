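id	name	region	is_aggregate	q_GSTM1	n_GSTM1	q_GSTT1	n_GSTT1
eAs	East Asia	Eastern Asia	1	0.521	8931	0.476	7875
eAs_Jap	Japan	Eastern Asia	0	0.501	2215	0.496	1518
eAs_Kor	Korea	Eastern Asia	0	0.527	3704	0.509	3641
eAs_Chi	China	Eastern Asia	0	0.535	2467	0.443	2355
eAs_Mon	Mongolia	Eastern Asia	0	0.464	207	0.256	207
seAs	South East Asia	South Eastern Asia	1	0.562	1666	0.351	890
seAs_Vie	Vietnam	South Eastern Asia	0	0.420	100	0.300	100
seAs_Phi	Philippines	South Eastern Asia	0	0.517	60	0.333	60
seAs_Ids	Indonesia	South Eastern Asia	0	0.556	162	0.414	162
seAs_S_M	Singapore-Malay	South Eastern Asia	0	0.653	167	0.383	167
sAs_Ind	India	Southern Asia India	1	0.296	4720	0.182	4570
Ind_Up	Uttar Pradesh	Southern Asia India	0	0.327	1107	0.174	1107
Ind_Wb	West Bengal	Southern Asia India	0	0.270	67	0.130	67
Ind_Guj	Gujarat	Southern Asia India	0	0.200	504	0.355	504
Ind_Mah	Maharashtra	Southern Asia India	0	0.299	2060	0.138	2060
Ind_Ap	Andhra Pradesh	Southern Asia India	0	0.359	370	0.254	370
Ind_Kar	Karnataka	Southern Asia India	0	0.258	260	0.191	110
Ind_Tn	Tamilnadu	Southern Asia India	0	0.235	200	0.188	200
Ind_Ker	Kerala	Southern Asia India	0	0.324	182	0.128	182
sAs_Afg	Afghanistan	Southern Asia	0	0.460	656	0.186	656
sAs_Iran	Iran	Southern Asia	0	0.406	NA	0.382	NA
sAs_Pak	Pakistan	Southern Asia	0	0.450	111	0.230	111
nEu	North Europe	Northern Europe	1	0.533	3686	0.165	2291
nEu_Swd	Sweden	Northern Europe	0	0.546	747	0.147	626
nEu_Fin	Finland	Northern Europe	0	0.469	482	0.130	385
nEu_Dnk	Denmark	Northern Europe	0	0.536	537	0.129	358
nEu_Uk	UK	Northern Europe	0	0.578	1122	0.205	922
wEu	West Europe	Western Europe	1	0.515	6486	0.183	5562
wEu_Ned	Netherlands	Western Europe	0	0.504	419	0.229	419
wEu_Ger	Germany	Western Europe	0	0.516	3054	0.173	3054
wEu_Fra	France	Western Europe	0	0.534	1184	0.168	512
sEu	South Europe	Southern Europe	1	0.509	3770	0.195	2660
sEu_Ita	Italy	Southern Europe	0	0.494	810	0.163	553
sEu_Spa	Spain	Southern Europe	0	0.504	1132	0.221	1121
sEu_Sln	Slovenia	Southern Europe	0	0.520	102	0.255	102
sEu_Gre	Greece	Southern Europe	0	0.520	171	0.099	171
eEu	East Europe	Eastern Europe	1	0.511	1184	0.188	1169
eEu_Cze	Czech Republic	Eastern Europe	0	0.567	67	0.224	67
eEu_Bul	Bulgaria	Eastern Europe	0	0.518	112	0.161	112
eEu_Pol	Poland	Eastern Europe	0	0.511	321	0.193	321
eEu_Slk	Slovakia	Eastern Europe	0	0.512	332	0.180	322
eEu_Rus	Russia	Eastern Europe	0	0.497	352	0.193	352
nAf_Egt	Egypt	Africa	0	0.555	200	0.295	200
wAf_Nig	Nigeria	Africa	0	0.300	300	0.370	300
sAf_Xho	Xhosa	Africa	0	0.211	128	0.406	128
sAf_Nam	Namibia	Africa	0	0.112	134	0.358	134
mAf_Cam	Cameroon	Africa	0	0.278	126	0.468	126
eAf_Eth	Ethiopia	Africa	0	0.435	153	0.373	153
eAf_Som	Somalia	Africa	0	0.400	100	0.440	100
eAf_Zim	Zimbabwe	Africa	0	0.240	150	0.260	150
wAs_Cau	Caucasian	Western Asia	0	0.529	2714	0.197	1223
sAm_Brz	Brazil	South America	0	0.397	794	0.267	794
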