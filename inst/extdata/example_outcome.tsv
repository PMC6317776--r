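rsid	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	info	n
rs00001	1	1000	C	T	0.199537	-0.105463	0.021064	5.53446e-07	1	31190
rs00002	1	2000	T	C	0.757861	-0.0361096	0.0196515	0.0661367	1	31190
rs00003	1	3000	T	G	0.848801	-0.0723461	0.0234988	0.00207897	1	31190
rs00004	1	4000	T	C	0.609219	0.115372	0.0172532	2.2786e-11	1	31190
rs00005	1	5000	G	C	0.215977	-0.018969	0.0204576	0.353806	1	31190
rs00006	1	6000	G	C	0.867786	-0.00713871	0.024853	0.77393	1	31190
rs00007	1	7000	C	A	0.240853	-0.0278798	0.0196872	0.156736	1	31190
rs00008	1	8000	T	G	0.144342	-0.106578	0.0239539	8.61621e-06	1	31190
rs00009	1	9000	A	G	0.274897	0.0404447	0.0188555	0.0319547	1	31190
rs00010	1	10000	A	C	0.402479	-0.048926	0.0171663	0.00437023	1	31190
rs00011	1	11000	A	C	0.187778	-0.0518712	0.0215558	0.0161121	1	31190
rs00012	1	12000	G	A	0.774923	-0.0286085	0.0201571	0.155819	1	31190
rs00013	1	13000	C	A	0.241064	0.0515704	0.0196814	0.00878615	1	31190
rs00014	1	14000	G	A	0.432457	0.0362981	0.0169923	0.0326676	1	31190
rs00015	1	15000	G	T	0.862845	0.00806994	0.024471	0.74157	1	31190
rs00016	1	16000	T	A	0.86517	0.0836707	0.0246479	0.000687192	1	31190
rs00017	1	17000	T	G	0.734343	-0.0121016	0.0190596	0.525471	1	31190
rs00018	1	18000	T	C	0.513322	-0.00554329	0.0168426	0.742062	1	31190
rs00019	1	19000	G	A	0.732028	-0.017293	0.0190071	0.362919	1	31190
rs00020	1	20000	G	T	0.847808	-0.0462494	0.0234357	0.0484437	1	31190
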