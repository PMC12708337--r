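#genome_length	15900
#or_majority	15200
#or_minority	15200
#dir_majority	increasing
#dir_minority	decreasing
gene	start	end	strand	category
ND2	200	1222	majority	ND
COX1	1475	3016	majority	CO
COX2	3082	3769	majority	CO
ATP8	3840	3998	majority	AT
ATP6	4005	4679	majority	AT
COX3	4687	5475	majority	CO
ND3	5545	5898	majority	ND
ND5	6000	7719	minority	ND
ND4	7790	9128	minority	ND
ND4L	9135	9425	minority	ND
ND6	9500	10024	majority	ND
CYTB	10030	11163	majority	CO
ND1	11240	12178	minority	ND
16S	12250	13574	minority	rRNA
12S	13600	14384	minority	rRNA
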