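rsid	rs00001	rs00002	rs00003	rs00004	rs00005	rs00006	rs00007	rs00008	rs00009	rs00010	rs00011	rs00012	rs00013	rs00014	rs00015	rs00016	rs00017	rs00018	rs00019	rs00020
rs00001	1	0.15	0.15	0.15	0.15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs00002	0.15	1	0.15	0.15	0.15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs00003	0.15	0.15	1	0.15	0.15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs00004	0.15	0.15	0.15	1	0.15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs00005	0.15	0.15	0.15	0.15	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs00006	0	0	0	0	0	1	0.15	0.15	0.15	0.15	0	0	0	0	0	0	0	0	0	0
rs00007	0	0	0	0	0	0.15	1	0.15	0.15	0.15	0	0	0	0	0	0	0	0	0	0
rs00008	0	0	0	0	0	0.15	0.15	1	0.15	0.15	0	0	0	0	0	0	0	0	0	0
rs00009	0	0	0	0	0	0.15	0.15	0.15	1	0.15	0	0	0	0	0	0	0	0	0	0
rs00010	0	0	0	0	0	0.15	0.15	0.15	0.15	1	0	0	0	0	0	0	0	0	0	0
rs00011	0	0	0	0	0	0	0	0	0	0	1	0.15	0.15	0.15	0.15	0	0	0	0	0
rs00012	0	0	0	0	0	0	0	0	0	0	0.15	1	0.15	0.15	0.15	0	0	0	0	0
rs00013	0	0	0	0	0	0	0	0	0	0	0.15	0.15	1	0.15	0.15	0	0	0	0	0
rs00014	0	0	0	0	0	0	0	0	0	0	0.15	0.15	0.15	1	0.15	0	0	0	0	0
rs00015	0	0	0	0	0	0	0	0	0	0	0.15	0.15	0.15	0.15	1	0	0	0	0	0
rs00016	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0.15	0.15	0.15	0.15
rs00017	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.15	1	0.15	0.15	0.15
rs00018	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.15	0.15	1	0.15	0.15
rs00019	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.15	0.15	0.15	1	0.15
rs00020	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.15	0.15	0.15	0.15	1
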