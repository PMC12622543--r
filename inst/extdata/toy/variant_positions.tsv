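variant_id	chrom	pos	ref	alt
chr01_000046208	chr01	46208	T	G
chr01_000054425	chr01	54425	G	A
chr01_000061413	chr01	61413	T	A
chr01_000074362	chr01	74362	A	G
chr01_000409956	chr01	409956	T	G
chr01_000585893	chr01	585893	A	G
chr01_000623844	chr01	623844	T	A
chr01_000626546	chr01	626546	G	A
chr01_000859668	chr01	859668	C	A
chr01_000964632	chr01	964632	C	A
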