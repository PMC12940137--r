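variable	group	count	denom	pct_printed
women	0	38	47	80.9
women	1	38	48	79.2
women	2	45	51	88.2
women	D	28	46	60.9
menopause	0	19	38	50.0
menopause	1	20	38	52.6
menopause	2	26	45	57.8
menopause	D	21	28	75.0
education_lt2y	0	3	47	6.4
education_lt2y	1	8	48	16.7
education_lt2y	2	11	51	21.6
education_lt2y	D	19	46	41.3
antihypertensives	D	16	45	35.6
oral_antidiabetics	D	31	45	68.9
metformin	D	25	45	55.6
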