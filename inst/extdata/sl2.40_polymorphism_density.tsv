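chromosome	partition	n_polymorphisms	covered
SL2.40ch01	E	4152	17310734
SL2.40ch02	E	4123	14644412
SL2.40ch03	E	3700	11678941
SL2.40ch04	E	2863	6261540
SL2.40ch05	E	969	5377576
SL2.40ch06	E	2417	10621719
SL2.40ch07	E	3504	8336310
SL2.40ch08	E	2113	9541847
SL2.40ch09	E	1932	6047365
SL2.40ch10	E	1302	5473701
SL2.40ch11	E	1694	6855876
SL2.40ch12	E	2161	8119058
SL2.40ch01	H	12319	39941033
SL2.40ch02	H	10694	15405507
SL2.40ch03	H	10408	32458031
SL2.40ch04	H	9995	34993238
SL2.40ch05	H	30951	31099727
SL2.40ch06	H	5134	19672865
SL2.40ch07	H	8347	35988229
SL2.40ch08	H	8562	33980702
SL2.40ch09	H	10231	40376427
SL2.40ch10	H	9209	37964128
SL2.40ch11	H	14937	27534109
SL2.40ch12	H	10075	36150348
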