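rsid	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	info	n
rs00001	1	1000	A	G	0.800463	0.257918	0.00323029	1e-300	1	300000
rs00002	1	2000	G	A	0.242139	0.10295	0.00301368	9.27130999999999e-256	1	300000
rs00003	1	3000	A	C	0.848801	-0.117063	0.00360368	1.7723e-231	1	300000
rs00004	1	4000	A	G	0.609219	0.195903	0.00264588	1e-300	1	300000
rs00005	1	5000	C	G	0.215977	-0.0401417	0.0031373	1.74892e-37	1	300000
rs00006	1	6000	C	G	0.867786	-0.0162953	0.00381135	1.90729e-05	1	300000
rs00007	1	7000	G	T	0.240853	-0.085164	0.00301915	4.67857e-175	1	300000
rs00008	1	8000	A	C	0.144342	-0.133248	0.00367348	4.29813e-288	1	300000
rs00009	1	9000	A	G	0.274897	0.0729461	0.00289161	2.03478e-140	1	300000
rs00010	1	10000	G	T	0.597521	0.146301	0.00263255	1e-300	1	300000
rs00011	1	11000	G	T	0.812222	0.0522135	0.00330571	3.3712e-56	1	300000
rs00012	1	12000	G	A	0.774923	-0.0462692	0.00309122	1.18953e-50	1	300000
rs00013	1	13000	T	G	0.758936	-0.115625	0.00301825	1e-300	1	300000
rs00014	1	14000	C	T	0.432457	0.0910741	0.00260587	1.31583e-267	1	300000
rs00015	1	15000	G	T	0.862845	0.016025	0.00375277	1.95324e-05	1	300000
rs00016	1	16000	T	A	0.13483	-0.214053	0.0037799	1e-300	1	300000
rs00017	1	17000	G	T	0.265657	0.091268	0.0029229	4.85792e-214	1	300000
rs00018	1	18000	G	A	0.486678	0.00962714	0.00258291	0.000193578	1	300000
rs00019	1	19000	C	T	0.732028	-0.0688038	0.00291485	3.45657e-123	1	300000
rs00020	1	20000	A	C	0.152192	0.118281	0.00359401	1.54809e-237	1	300000
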