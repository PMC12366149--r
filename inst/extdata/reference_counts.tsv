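dataset	caller	svtype	tp	fp	fn	precision	recall	f1
hg002_giab_35x	breakdancer	DEL	902	581	3149	0.61	0.22	0.33
hg002_giab_35x	breakdancer	INS	2	7	5211	0.22	NA	NA
hg002_giab_35x	delly	DEL	2251	402	1800	0.85	0.56	0.67
hg002_giab_35x	delly	INS	352	45	4861	0.89	0.07	0.13
hg002_giab_35x	insurveyor	INS	1800	131	3413	0.93	0.35	0.50
hg002_giab_35x	lumpy	DEL	2055	132	1996	0.94	0.51	0.66
hg002_giab_35x	lumpy	INS	22	15	5191	0.59	NA	NA
hg002_giab_35x	manta	DEL	2649	97	1402	0.96	0.65	0.78
hg002_giab_35x	manta	INS	571	55	4642	0.91	0.11	0.20
hg002_giab_35x	pindel	DEL	2617	504	1434	0.84	0.65	0.73
hg002_giab_35x	pindel	INS	1061	668	4152	0.61	0.20	0.31
hg002_giab_35x	tardis	DEL	1278	28	2773	0.98	0.32	0.48
hg002_giab_35x	tardis	INS	414	471	4799	0.47	0.08	0.14
hg002_giab_35x	union	DEL	3207	967	844	0.77	0.79	0.78
hg002_giab_35x	union	INS	2518	1254	2695	0.67	0.48	0.56
hg002_cmrg	union	DEL	45	68	53	NA	NA	0.43
hg002_cmrg	union	INS	29	46	89	NA	NA	0.30
hg00514	union	DEL	4938	11460	3645	NA	NA	0.40
hg00514	union	INS	5509	18565	7932	NA	NA	0.29
hg00733	union	DEL	5037	11958	3734	NA	NA	0.39
hg00733	union	INS	5633	22277	7970	NA	NA	0.27
na19240	union	DEL	5832	12434	4442	NA	NA	0.41
na19240	union	INS	6448	21430	9003	NA	NA	0.30
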