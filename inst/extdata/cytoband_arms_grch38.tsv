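chr1	0	123400000	p11	gneg
chr1	123400000	248956422	q11	gneg
chr2	0	93900000	p11	gneg
chr2	93900000	242193529	q11	gneg
chr3	0	90900000	p11	gneg
chr3	90900000	198295559	q11	gneg
chr4	0	50000000	p11	gneg
chr4	50000000	190214555	q11	gneg
chr5	0	48800000	p11	gneg
chr5	48800000	181538259	q11	gneg
chr6	0	59800000	p11	gneg
chr6	59800000	170805979	q11	gneg
chr7	0	60100000	p11	gneg
chr7	60100000	159345973	q11	gneg
chr8	0	45200000	p11	gneg
chr8	45200000	145138636	q11	gneg
chr9	0	43000000	p11	gneg
chr9	43000000	138394717	q11	gneg
chr10	0	39800000	p11	gneg
chr10	39800000	133797422	q11	gneg
chr11	0	53400000	p11	gneg
chr11	53400000	135086622	q11	gneg
chr12	0	35500000	p11	gneg
chr12	35500000	133275309	q11	gneg
chr13	0	17700000	p11	gneg
chr13	17700000	114364328	q11	gneg
chr14	0	17200000	p11	gneg
chr14	17200000	107043718	q11	gneg
chr15	0	19000000	p11	gneg
chr15	19000000	101991189	q11	gneg
chr16	0	36800000	p11	gneg
chr16	36800000	90338345	q11	gneg
chr17	0	25100000	p11	gneg
chr17	25100000	83257441	q11	gneg
chr18	0	18500000	p11	gneg
chr18	18500000	80373285	q11	gneg
chr19	0	26200000	p11	gneg
chr19	26200000	58617616	q11	gneg
chr20	0	28100000	p11	gneg
chr20	28100000	64444167	q11	gneg
chr21	0	12000000	p11	gneg
chr21	12000000	46709983	q11	gneg
chr22	0	15000000	p11	gneg
chr22	15000000	50818468	q11	gneg
chrX	0	61000000	p11	gneg
chrX	61000000	156040895	q11	gneg
chrY	0	10400000	p11	gneg
chrY	10400000	57227415	q11	gneg
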