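id	length	expansion	count	weight	run_length
a	12	GFDECBALKJIH	1482	17789	343
b	19	aGFDECBA	20	1611	219
c	16	KJIHa	18	1527	163
d	22	bLKJ	8	1482	136
e	3	NIH	8	1474	120
f	17	Lc	9	1469	109
g	17	Gc	8	1468	101
h	20	bL	7	1459	94
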