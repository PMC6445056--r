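##fileformat=VCFv4.2
##contig=<ID=chr1,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	A1	A2	A3	B1	B2
chr1	101	.	A	G	.	PASS	.	GT	0/0	0/1	0/0	1/1	1/1
chr1	205	.	C	T	.	PASS	.	GT	./.	0/1	1/1	0/0	./.
chr1	300	.	G	A,T	.	PASS	.	GT	0/0	0/1	0/2	1/1	0/0
chr1	351	.	AT	A	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/0
chr1	400	.	T	C	.	PASS	.	GT	0/0	0/0	0/0	0/0	1/1
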