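rsid_a	rsid_b	r2
rs00001	rs00002	0.15
rs00001	rs00003	0.15
rs00002	rs00003	0.15
rs00001	rs00004	0.15
rs00002	rs00004	0.15
rs00003	rs00004	0.15
rs00001	rs00005	0.15
rs00002	rs00005	0.15
rs00003	rs00005	0.15
rs00004	rs00005	0.15
rs00006	rs00007	0.15
rs00006	rs00008	0.15
rs00007	rs00008	0.15
rs00006	rs00009	0.15
rs00007	rs00009	0.15
rs00008	rs00009	0.15
rs00006	rs00010	0.15
rs00007	rs00010	0.15
rs00008	rs00010	0.15
rs00009	rs00010	0.15
rs00011	rs00012	0.15
rs00011	rs00013	0.15
rs00012	rs00013	0.15
rs00011	rs00014	0.15
rs00012	rs00014	0.15
rs00013	rs00014	0.15
rs00011	rs00015	0.15
rs00012	rs00015	0.15
rs00013	rs00015	0.15
rs00014	rs00015	0.15
rs00016	rs00017	0.15
rs00016	rs00018	0.15
rs00017	rs00018	0.15
rs00016	rs00019	0.15
rs00017	rs00019	0.15
rs00018	rs00019	0.15
rs00016	rs00020	0.15
rs00017	rs00020	0.15
rs00018	rs00020	0.15
rs00019	rs00020	0.15
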