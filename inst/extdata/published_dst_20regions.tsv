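id	eAf_Zim	sAf_Nam	sAf_Xho	mAf_Cam	wAf_Nig	sAs_Ind	sAm_Brz	eAf_Som	sAs_Iran	eAf_Eth	sAs_Pak	sAs_Afg	sEu	eEu	wEu	eAs	wAs_Cau	nEu	nAf_Egt	seAs
eAf_Zim
sAf_Nam	0.019641
sAf_Xho	0.018002	0.007702
mAf_Cam	0.036741	0.028132	0.006642
wAf_Nig	0.011698	0.025018	0.007576	0.009135
sAs_Ind	0.007203	0.050393	0.046757	0.068305	0.027352
sAm_Brz	0.019686	0.071517	0.047429	0.050077	0.017980	0.012453
eAf_Som	0.047449	0.069856	0.031371	0.014241	0.013198	0.062987	0.027019
sAs_Iran	0.033673	0.067958	0.033278	0.022080	0.010096	0.040405	0.011558	0.003247
eAf_Eth	0.041147	0.083845	0.045069	0.031565	0.016495	0.043599	0.010910	0.005520	0.000882
sAs_Pak	0.037341	0.107807	0.078333	0.079443	0.037756	0.020062	0.003628	0.042121	0.021916	0.017784
sAs_Afg	0.044754	0.124665	0.097123	0.102102	0.052050	0.021304	0.008620	0.060075	0.035118	0.029735	0.001511
sEu	0.064578	0.155621	0.119309	0.117913	0.066300	0.036737	0.015131	0.064593	0.039712	0.031804	0.003921	0.002064
eEu	0.066210	0.158879	0.122818	0.122007	0.069013	0.037348	0.016296	0.067829	0.042182	0.034056	0.004511	0.002175	0.000038
wEu	0.068642	0.163151	0.126834	0.126154	0.072004	0.038764	0.017691	0.070734	0.044494	0.036072	0.005254	0.002530	0.000130	0.000031
eAs	0.112148	0.157404	0.093422	0.056769	0.057067	0.119908	0.055200	0.015755	0.021559	0.017606	0.060443	0.079037	0.071492	0.074740	0.077050
wAs_Cau	0.114150	0.162684	0.097673	0.060689	0.059434	0.120082	0.054782	0.017359	0.022368	0.017846	0.058754	0.076677	0.068473	0.071609	0.073799	0.000099
nEu	0.079650	0.181776	0.143916	0.143304	0.084726	0.045716	0.023990	0.082505	0.054067	0.044384	0.008885	0.004708	0.001084	0.000751	0.000480	0.085835	0.082097
nAf_Egt	0.087395	0.174577	0.121158	0.102434	0.066203	0.066198	0.023311	0.043045	0.028058	0.019145	0.013337	0.017263	0.009810	0.010731	0.011240	0.032074	0.029501	0.013382
seAs	0.098593	0.178065	0.117995	0.091480	0.065434	0.083794	0.031293	0.033343	0.024411	0.015989	0.023986	0.031810	0.022755	0.024282	0.025180	0.016697	0.014669	0.028655	0.002821
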