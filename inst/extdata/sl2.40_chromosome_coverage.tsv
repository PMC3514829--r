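chromosome	partition	length	n_contigs	n_clones	covered
SL2.40ch01	E	27903720	100	533	17310734
SL2.40ch02	E	24734122	78	504	14644412
SL2.40ch03	E	16423960	45	401	11678941
SL2.40ch04	E	13871288	34	231	6261540
SL2.40ch05	E	10836573	32	170	5377576
SL2.40ch06	E	17576248	52	339	10621719
SL2.40ch07	E	17480118	53	224	8336310
SL2.40ch08	E	15552430	55	279	9541847
SL2.40ch09	E	10522300	37	176	6047365
SL2.40ch10	E	9129273	25	197	5473701
SL2.40ch11	E	11175203	45	184	6855876
SL2.40ch12	E	12034427	44	317	8119058
SL2.40ch01	H	62400524	175	1000	39941033
SL2.40ch02	H	25184172	74	391	15405507
SL2.40ch03	H	48416754	147	903	32458031
SL2.40ch04	H	50193024	131	1022	34993238
SL2.40ch05	H	54184865	169	752	31099727
SL2.40ch06	H	28465388	76	544	19672865
SL2.40ch07	H	47788503	135	959	35988229
SL2.40ch08	H	47480227	150	856	33980702
SL2.40ch09	H	57139791	149	1209	40376427
SL2.40ch10	H	55705032	159	1056	37964128
SL2.40ch11	H	42210822	128	746	27534109
SL2.40ch12	H	53451826	155	992	36150348
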