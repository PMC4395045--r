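id	latitude	longitude
sAf_Xho	-30.33	22.56
eAf_Zim	-19.0	29.9
nAf_Egt	26.49	30.48
eAf_Eth	9.8	40.29
wAf_Nig	9.4	8.4
mAf_Cam	7.22	12.21
eAf_Som	5.9	46.11
sAf_Nam	-22.57	18.29
sAs_Iran	32.25	53.41
sAs_Pak	30.22	69.20
sAs_Afg	33.56	67.42
sAs_Ind	20.35	78.57
eAs	22.16	114.14
seAs	11.35	121.37
wAs_Cau	43	43.45
nEu	62.16	12.20
wEu	46.12	1.15
sEu	41.16	-1.12
eEu	59.80	36.29
sAm_Brz	-14.14	-51.55
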