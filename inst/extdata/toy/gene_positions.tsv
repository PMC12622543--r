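gene_id	chrom	start	end	strand
gene0001	chr01	724625	727625	-
gene0002	chr01	291584	294584	-
gene0003	chr01	9	3009	+
gene0004	chr01	927202	930202	+
gene0005	chr01	929374	932374	+
gene0006	chr01	487174	490174	+
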