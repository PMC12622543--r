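accession	chr01_000046208	chr01_000054425	chr01_000061413	chr01_000074362	chr01_000409956	chr01_000585893	chr01_000623844	chr01_000626546	chr01_000859668	chr01_000964632
ACC0001	0	0	0	0	2	0	0	0	0	0
ACC0002	2	2	2	2	2	0	0	0	0	0
ACC0003	2	2	2	0	2	0	0	0	0	2
ACC0004	0	0	0	0	0	2	0	0	0	0
ACC0005	0	0	0	2	0	2	0	0	0	0
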