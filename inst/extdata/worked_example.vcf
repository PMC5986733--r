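##fileformat=VCFv4.2
##source=founderhap
##contig=<ID=chr4,length=190214555>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S3	S4
chr4	117000000	.	G	A	.	.	.	GT:DP	0/1:40	0/0:38	0/0:45
chr4	120500000	.	A	C	.	.	.	GT:DP	1/1:40	0/1:38	0/1:45
chr4	121500000	.	T	G	.	.	.	GT:DP	0/0:40	0/1:38	0/0:45
chr4	122300000	.	C	T	.	.	.	GT:DP	1/1:40	0/1:38	1/1:45
chr4	122350000	.	G	T	.	.	.	GT:DP	1/1:40	1/1:38	0/1:45
chr4	122400000	.	A	G	.	.	.	GT:DP	1/1:40	1/1:38	1/1:45
chr4	122600000	.	C	A	.	.	.	GT:DP	1/1:40	1/1:38	1/1:45
chr4	122722620	.	T	C	.	.	.	GT:DP	1/1:34	1/1:41	1/1:52
chr4	122800000	.	G	C	.	.	.	GT:DP	1/1:40	0/1:7	1/1:45
chr4	122900000	.	AT	A	.	.	.	GT:DP	0/1:40	0/1:38	0/1:45
chr4	123000000	.	T	A	.	.	.	GT:DP	1/1:40	1/1:38	1/1:45
chr4	123200000	.	G	T	.	.	.	GT:DP	1/1:40	1/1:38	1/1:45
chr4	123250000	.	A	T	.	.	.	GT:DP	1/1:40	1/1:38	0/1:45
chr4	123300000	.	C	G	.	.	.	GT:DP	0/0:40	0/1:38	0/0:45
chr4	124500000	.	T	C	.	.	.	GT:DP	1/1:40	0/1:38	0/1:45
chr4	128000000	.	A	G	.	.	.	GT:DP	0/1:40	0/0:38	0/0:45
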