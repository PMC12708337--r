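#genome_length	16569
#or_majority	110
#or_minority	5721
#dir_majority	decreasing
#dir_minority	increasing
gene	start	end	strand	category
12S	648	1601	majority	rRNA
16S	1671	3229	majority	rRNA
ND1	3307	4262	majority	ND
ND2	4470	5511	majority	ND
COX1	5904	7445	majority	CO
COX2	7586	8269	majority	CO
ATP8	8366	8572	majority	AT
ATP6	8580	9260	majority	AT
COX3	9268	10051	majority	CO
ND3	10059	10404	majority	ND
ND4L	10470	10766	majority	ND
ND4	10770	12147	majority	ND
ND5	12337	14148	majority	ND
ND6	14149	14673	minority	ND
CYTB	14747	15887	majority	CO
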