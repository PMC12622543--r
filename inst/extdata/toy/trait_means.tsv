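accession	year1	year2
ACC0001	-0.436088013713046	0.206880497449584
ACC0002	-0.0848191047836333	1.5973047130635
ACC0003	0.507995771232328	-0.160402730907372
ACC0004	-1.49966366073561	-1.58827769061723
ACC0005	0.695492075036138	1.15890737007501
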