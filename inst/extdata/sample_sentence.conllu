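# sent_id = 1
1	The	_	DT	_	_	3	det	_	_
2	young	_	JJ	_	_	3	amod	_	_
3	lad	_	NN	_	_	5	nsubj	_	_
4	is	_	VBZ	_	_	5	aux	_	_
5	going	_	VBG	_	_	0	root	_	_
6	to	_	TO	_	_	7	mark	_	_
7	fall	_	VB	_	_	5	xcomp	_	_
8	from	_	IN	_	_	10	case	_	_
9	the	_	DT	_	_	10	det	_	_
10	stool	_	NN	_	_	7	obl	_	_
11	.	_	PUNCT	_	_	5	punct	_	_
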