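accession	met001	met002	met003	met004
ACC0001	-0.464047793181334	0.526079326582603	-1.860610492692	-1.73069667441629
ACC0002	0.401795428081812	1.32208445997313	0.134253633639344	0.840811642938016
ACC0003	0.0360927291080387	0.127944871311502	0.162070679704173	0.100066586205552
ACC0004	0.463714150707484	-0.372147981487669	1.07349910018523	0.276620803634853
ACC0005	-0.770758068671878	0.794999087194457	-0.0313295927462564	1.36898240932856
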