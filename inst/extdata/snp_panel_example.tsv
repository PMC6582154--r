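chrom	pos	ref	alt
chrA01	533686	A	G
chrA01	534210	C	T
chrA01	601455	G	A
chrA02	10233	T	C
chrA02	48211	A	T
chrA03	77109	C	G
chrA07	910344	G	T
chrC01	15987	T	A
chrC02	224860	A	C
chrC04	388412	C	A
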