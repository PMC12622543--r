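accession	gene0001	gene0002	gene0003	gene0004	gene0005	gene0006
ACC0001	-0.964273867813464	-0.787996463925867	0.204543345596112	1.48750889415408	1.43960779095166	0.0513276553520358
ACC0002	0.41189574136057	-0.823296945086647	0.705075863253464	-1.67538102997322	-0.27258319959358	0.0318465040274029
ACC0004	-0.0645697635816234	-0.452863709260488	-1.49316486101357	0.403207996167248	-0.0477901724126997	-0.568779241831307
ACC0005	0.908752262987101	1.44713118633593	0.435382184562081	-0.37935071725706	-0.739258715435346	-0.0714667652283312
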