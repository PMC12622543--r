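##fileformat=VCFv4.2
##source=mqtlnet
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ACC0001	ACC0002	ACC0003	ACC0004	ACC0005
chr01	46208	chr01_000046208	T	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/0
chr01	54425	chr01_000054425	G	A	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/0
chr01	61413	chr01_000061413	T	A	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/0
chr01	74362	chr01_000074362	A	G	.	PASS	.	GT	0/0	1/1	0/0	0/0	1/1
chr01	409956	chr01_000409956	T	G	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0
chr01	585893	chr01_000585893	A	G	.	PASS	.	GT	0/0	0/0	0/0	1/1	1/1
chr01	623844	chr01_000623844	T	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0
chr01	626546	chr01_000626546	G	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0
chr01	859668	chr01_000859668	C	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0
chr01	964632	chr01_000964632	C	A	.	PASS	.	GT	0/0	0/0	1/1	0/0	0/0
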