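##fileformat=VCFv4.2
##source=hand-built fixture exercising the SNP filtering rules
##contig=<ID=ctg1,length=1000000>
##FILTER=<ID=q10,Description="Quality below 10">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SIM
ctg1	5	.	A	G	60	PASS	.	GT	0/1
ctg1	10	.	C	T	60	.	.	GT	0/1
ctg1	20	.	T	A	60	PASS	.	GT	1/1
ctg1	100	.	AT	A	60	PASS	.	GT	0/1
ctg1	200	.	G	GA	60	PASS	.	GT	0/1
ctg1	300	.	G	A,T	60	PASS	.	GT	1/2
ctg1	400	.	C	G	60	q10	.	GT	0/1
ctg1	500	.	T	C	60	PASS	.	GT	./.
ctg1	600	.	A	C	60	PASS	.	GT	.
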