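accession	met001	met002	met003	met004
ACC0001	0.192593720276116	-0.124105888324988	-1.29860439411902	-1.09338935668742
ACC0002	0.81999607161162	0.753100544806	0.0679008893645376	0.141283211455398
ACC0003	-1.45934119100682	-0.903434820450773	1.05366121871612	0.131602150214826
ACC0004	0.489684448354292	-0.658403576526745	0.107277642432486	-0.806875764168822
ACC0005	-1.17955748559299	0.831937293848928	-0.440509625169472	0.360819980485854
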