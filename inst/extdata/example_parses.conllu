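# doc_id = 10340919
1	The	_	DT	DT	_	2	det	_	start=8|end=11
2	effects	_	NNS	NNS	_	6	nsubjpass	_	start=12|end=19
3	of	_	IN	IN	_	0	_	_	start=20|end=22
4	meloxicam	_	NN	NN	_	2	prep_of	_	start=23|end=32
5	were	_	VBD	VBD	_	6	auxpass	_	start=33|end=37
6	compared	_	VBN	VBN	_	0	_	_	start=38|end=46
7	with	_	IN	IN	_	0	_	_	start=47|end=51
8	those	_	DT	DT	_	6	prep_with	_	start=52|end=57
9	of	_	IN	IN	_	0	_	_	start=58|end=60
10	diclofenac	_	NN	NN	_	8	prep_of	_	start=61|end=71
11	,	_	,	,	_	10	punct	_	start=71|end=72
12	a	_	DT	DT	_	15	det	_	start=73|end=74
13	nonselective	_	JJ	JJ	_	15	amod	_	start=75|end=87
14	COX	_	NN	NN	_	15	nn	_	start=88|end=91
15	inhibitor	_	NN	NN	_	10	appos	_	start=92|end=101
16	.	_	.	.	_	6	punct	_	start=101|end=102
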