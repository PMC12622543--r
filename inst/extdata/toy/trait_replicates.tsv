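accession	year	replicate	value
ACC0001	1	1	-0.493656083228915
ACC0002	1	1	-0.143253675090337
ACC0003	1	1	-0.220315464785328
ACC0004	1	1	-1.69007362816654
ACC0005	1	1	0.92227983956794
ACC0001	1	2	-0.378519944197176
ACC0002	1	2	-0.0263845344769292
ACC0003	1	2	1.23630700724998
ACC0004	1	2	-1.30925369330467
ACC0005	1	2	0.468704310504337
ACC0001	2	1	0.600967458937765
ACC0002	2	1	0.981766288886176
ACC0003	2	1	0.425090633890817
ACC0004	2	1	-1.34252397503098
ACC0005	2	1	1.08370638413068
ACC0001	2	2	-0.187206464038598
ACC0002	2	2	2.21284313724082
ACC0003	2	2	-0.745896095705561
ACC0004	2	2	-1.83403140620349
ACC0005	2	2	1.23410835601934
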