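##fileformat=VCFv4.2
##source=synthetic example for pgxkit documentation
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE_A	SAMPLE_B
6	52668477	rs3957357	C	T	.	PASS	.	GT	1/1	0/1
6	160670282	rs316019	A	C	.	PASS	.	GT	1/1	0/1
10	96405502	rs2292566	A	G	.	PASS	.	GT	0/0	0/1
10	96541616	rs4244285	A	G	.	PASS	.	GT	0/0	1/1
10	96702047	rs1799853	C	T	.	PASS	.	GT	0/1	0/0
16	31107689	rs9923231	A	G	.	PASS	.	GT	0/0	1/1
17	7579472	rs1042522	C	G	.	PASS	.	GT	0/0	0/1
19	15990431	rs2108622	C	T	.	PASS	.	GT	1/1	0/0
19	45923653	rs11615	A	G	.	PASS	.	GT	1/1	0/1
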