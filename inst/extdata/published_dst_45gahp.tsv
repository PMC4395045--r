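id	eAf_Zim	sAf_Nam	Ind_Guj	sAf_Xho	Ind_Tn	Ind_Kar	Ind_Wb	mAf_Cam	Ind_Mah	wAf_Nig	Ind_Ker	Ind_Up	Ind_Ap	sAm_Brz
eAf_Zim
sAf_Nam	0.019641
Ind_Guj	0.008566	0.004982
sAf_Xho	0.018002	0.007702	0.002144
Ind_Tn	0.003500	0.033450	0.022055	0.037140
Ind_Kar	0.003729	0.037771	0.023632	0.038408	0.000355
Ind_Wb	0.012420	0.058122	0.041785	0.061245	0.003252	0.002526
mAf_Cam	0.036741	0.028132	0.014999	0.006642	0.063507	0.062461	0.090338
Ind_Mah	0.013628	0.064129	0.044263	0.063067	0.004934	0.003307	0.000574	0.088816
wAf_Nig	0.011698	0.025018	0.007718	0.007576	0.026876	0.025085	0.042346	0.009135	0.040441
Ind_Ker	0.018509	0.075817	0.052630	0.072183	0.008654	0.006243	0.002038	0.096709	0.000540	0.045207
Ind_Up	0.011897	0.062884	0.039784	0.055683	0.006375	0.003826	0.003100	0.075196	0.001229	0.031146	0.001306
Ind_Ap	0.011155	0.056511	0.029903	0.039082	0.013492	0.009762	0.014788	0.047057	0.011066	0.014791	0.011238	0.005068
sAm_Brz	0.019686	0.071517	0.039623	0.047429	0.023229	0.018123	0.023228	0.050077	0.017729	0.017980	0.016579	0.009579	0.001318
eAf_Som	0.047449	0.069856	0.039132	0.031371	0.071354	0.065680	0.087771	0.014241	0.080505	0.013198	0.082462	0.062745	0.031855	0.027019
sAs_Iran	0.033673	0.067958	0.035776	0.033278	0.050368	0.044624	0.060441	0.022080	0.053470	0.010096	0.054000	0.038840	0.015631	0.011558
seAs_Vie	0.027183	0.078906	0.043887	0.048612	0.034281	0.028238	0.035694	0.045118	0.028849	0.017602	0.027294	0.018065	0.004738	0.001318
eAf_Eth	0.041147	0.083845	0.047123	0.045069	0.056782	0.049923	0.064060	0.031565	0.055751	0.016495	0.054832	0.040296	0.016788	0.010910
sAs_Pak	0.037341	0.107807	0.067666	0.078333	0.036617	0.029669	0.029982	0.079443	0.022419	0.037756	0.018481	0.013929	0.007683	0.003628
sAs_Afg	0.044754	0.124665	0.082681	0.097123	0.039341	0.032172	0.028470	0.102102	0.020874	0.052050	0.015882	0.014104	0.012496	0.008620
eAs_Mon	0.041766	0.111479	0.069331	0.077606	0.043779	0.036213	0.038385	0.074231	0.029918	0.036336	0.025780	0.019540	0.009564	0.004097
nEu_Fin	0.056413	0.147166	0.103438	0.122646	0.045284	0.037978	0.029516	0.132931	0.022041	0.072547	0.015927	0.017497	0.021698	0.018273
sEu_Ita	0.061485	0.153594	0.106118	0.122436	0.053407	0.045069	0.038414	0.126364	0.029524	0.070064	0.022816	0.022503	0.022062	0.016456
eEu_Rus	0.059262	0.147482	0.099679	0.113354	0.054266	0.045694	0.041407	0.113525	0.032070	0.062336	0.025631	0.023486	0.019501	0.013120
eAs_Jap	0.110350	0.146520	0.099722	0.084594	0.142570	0.132315	0.158417	0.048140	0.144938	0.053266	0.143253	0.118214	0.072885	0.059379
wEu_Ned	0.059823	0.144141	0.095375	0.105798	0.058632	0.049635	0.048197	0.101024	0.038141	0.055834	0.031893	0.027464	0.018923	0.011362
sEu_Spa	0.060246	0.145849	0.097044	0.108186	0.058185	0.049224	0.047092	0.104342	0.037126	0.057711	0.030768	0.026857	0.019275	0.011877
eEu_Pol	0.065713	0.157598	0.107503	0.121115	0.060599	0.051493	0.046757	0.119726	0.036775	0.067624	0.029742	0.027621	0.023028	0.015739
eEu_Slk	0.067544	0.161727	0.111408	0.126171	0.061054	0.051968	0.046119	0.126173	0.036234	0.071687	0.028989	0.027678	0.024546	0.017452
wEu_Ger	0.070266	0.166596	0.115586	0.130954	0.063009	0.053801	0.047246	0.131318	0.037254	0.075319	0.029750	0.028878	0.026377	0.019164
seAs_Phi	0.070253	0.140613	0.090160	0.090823	0.080995	0.070962	0.078774	0.072213	0.066801	0.045336	0.061492	0.049833	0.027442	0.016743
eEu_Bul	0.072759	0.171473	0.120080	0.136502	0.064240	0.055011	0.047413	0.138030	0.037460	0.079764	0.029721	0.029583	0.028364	0.021260
sEu_Sln	0.066941	0.151257	0.099936	0.107876	0.068535	0.058783	0.059143	0.098202	0.048016	0.056728	0.041428	0.035289	0.022831	0.013657
sEu_Gre	0.084181	0.192766	0.140787	0.162602	0.069434	0.060400	0.047888	0.171015	0.038494	0.101709	0.029929	0.033419	0.038936	0.032905
eAs_Kor	0.131072	0.171461	0.120063	0.103009	0.165454	0.153899	0.180971	0.061388	0.165744	0.067925	0.162999	0.136593	0.087477	0.071632
wAs_Cau	0.114150	0.162684	0.110741	0.097673	0.142911	0.131528	0.153814	0.060689	0.139138	0.059434	0.135556	0.112713	0.069730	0.054782
wEu_Fra	0.079786	0.181720	0.127681	0.143431	0.071836	0.061962	0.054405	0.142357	0.043640	0.084247	0.035309	0.034781	0.032085	0.023807
eAs_Chi	0.107068	0.162350	0.109199	0.098764	0.132097	0.120617	0.139605	0.064352	0.125031	0.057523	0.120667	0.100165	0.060995	0.046306
nEu_Dnk	0.086463	0.194885	0.140372	0.159569	0.074495	0.064731	0.053988	0.162804	0.043567	0.097621	0.034687	0.036500	0.038115	0.030493
nEu_Swd	0.088823	0.197255	0.141108	0.158695	0.078575	0.068343	0.058687	0.158719	0.047608	0.096026	0.038515	0.039288	0.038475	0.029849
nAf_Egt	0.087395	0.174577	0.117293	0.121158	0.093461	0.082045	0.085005	0.102434	0.071600	0.066203	0.063981	0.055069	0.035784	0.023311
seAs_Ids	0.110068	0.176501	0.119385	0.111506	0.131239	0.118996	0.134139	0.077907	0.118852	0.064351	0.112960	0.094840	0.058800	0.043301
eEu_Cze	0.093352	0.195596	0.135981	0.146458	0.091159	0.079672	0.075757	0.134876	0.062724	0.084693	0.053635	0.049608	0.038780	0.027114
nEu_Uk	0.100862	0.209262	0.147632	0.159813	0.096473	0.084651	0.078719	0.149197	0.065400	0.094779	0.055589	0.052818	0.043805	0.031824
seAs_S_M	0.171196	0.272027	0.195663	0.189285	0.188418	0.171818	0.180613	0.146069	0.160261	0.120939	0.148990	0.133165	0.096023	0.074061
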