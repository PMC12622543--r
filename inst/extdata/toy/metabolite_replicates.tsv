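accession	metabolite	year	replicate	value
ACC0001	met001	1	1	0.25802859450372
ACC0002	met001	1	1	1.196798628263
ACC0003	met001	1	1	-1.0024702110584
ACC0004	met001	1	1	0.920136776231793
ACC0005	met001	1	1	-0.782433909373495
ACC0001	met002	1	1	-0.165400317570613
ACC0002	met002	1	1	0.756963101720545
ACC0003	met002	1	1	-0.680642077031614
ACC0004	met002	1	1	-0.895887916821071
ACC0005	met002	1	1	0.924492521418945
ACC0001	met003	1	1	-1.22052712147447
ACC0002	met003	1	1	0.518891098656557
ACC0003	met003	1	1	-0.106105215438714
ACC0004	met003	1	1	-0.347414295422232
ACC0005	met003	1	1	-0.479820000627687
ACC0001	met004	1	1	-0.332563645777916
ACC0002	met004	1	1	0.612920349938177
ACC0003	met004	1	1	-0.711241184424886
ACC0004	met004	1	1	-0.890866784467097
ACC0005	met004	1	1	0.607886130156709
ACC0001	met001	1	2	0.127158846048512
ACC0002	met001	1	2	0.443193514960239
ACC0003	met001	1	2	-1.91621217095525
ACC0004	met001	1	2	0.0592321204767909
ACC0005	met001	1	2	-1.57668106181248
ACC0001	met002	1	2	-0.0828114590793619
ACC0002	met002	1	2	0.749237987891456
ACC0003	met002	1	2	-1.12622756386993
ACC0004	met002	1	2	-0.420919236232419
ACC0005	met002	1	2	0.739382066278911
ACC0001	met003	1	2	-1.37668166676357
ACC0002	met003	1	2	-0.383089319927482
ACC0003	met003	1	2	2.21342765287096
ACC0004	met003	1	2	0.561969580287205
ACC0005	met003	1	2	-0.401199249711257
ACC0001	met004	1	2	-1.85421506759693
ACC0002	met004	1	2	-0.330353927027382
ACC0003	met004	1	2	0.974445484854539
ACC0004	met004	1	2	-0.722884743870547
ACC0005	met004	1	2	0.113753830815
ACC0001	met001	2	1	-0.907757060699991
ACC0002	met001	2	1	0.317455205257819
ACC0003	met001	2	1	-0.326894026264316
ACC0004	met001	2	1	1.3044930620648
ACC0005	met001	2	1	-0.291191255999071
ACC0001	met002	2	1	1.02041787989621
ACC0002	met002	2	1	2.26243289754819
ACC0003	met002	2	1	0.218354381701725
ACC0004	met002	2	1	-0.0354170889996852
ACC0005	met002	2	1	0.706132778993785
ACC0001	met003	2	1	-1.61955088848496
ACC0002	met003	2	1	0.301301262602487
ACC0003	met003	2	1	-0.595675918975744
ACC0004	met003	2	1	1.48254284722709
ACC0005	met003	2	1	0.393332724924292
ACC0001	met004	2	1	-1.14112441949618
ACC0002	met004	2	1	1.01102984352217
ACC0003	met004	2	1	0.249703684114964
ACC0004	met004	2	1	0.356618577799922
ACC0005	met004	2	1	0.823462774846557
ACC0001	met001	2	2	-0.0203385256626773
ACC0002	met001	2	2	0.486135650905805
ACC0003	met001	2	2	0.399079484480393
ACC0004	met001	2	2	-0.37706476064983
ACC0005	met001	2	2	-1.25032488134468
ACC0001	met002	2	2	0.0317407732689956
ACC0002	met002	2	2	0.381736022398072
ACC0003	met002	2	2	0.0375353609212787
ACC0004	met002	2	2	-0.708878873975652
ACC0005	met002	2	2	0.883865395395128
ACC0001	met003	2	2	-2.10167009689904
ACC0002	met003	2	2	-0.0327939953237999
ACC0003	met003	2	2	0.919817278384091
ACC0004	met003	2	2	0.664455353143375
ACC0005	met003	2	2	-0.455991910416804
ACC0001	met004	2	2	-2.32026892933639
ACC0002	met004	2	2	0.670593442353863
ACC0003	met004	2	2	-0.0495705117038607
ACC0004	met004	2	2	0.196623029469784
ACC0005	met004	2	2	1.91450204381056
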