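gene	module	shift	rewired
g0001	1	2	TRUE
g0002	1	2	TRUE
g0003	1	2	FALSE
g0004	1	2	FALSE
g0005	1	2	FALSE
g0006	1	2	FALSE
g0007	1	2	FALSE
g0008	1	2	FALSE
g0009	1	2	FALSE
g0010	1	2	FALSE
g0011	2	-2	TRUE
g0012	2	-2	TRUE
g0013	2	-2	FALSE
g0014	2	-2	FALSE
g0015	2	-2	FALSE
g0016	2	-2	FALSE
g0017	2	-2	FALSE
g0018	2	-2	FALSE
g0019	2	-2	FALSE
g0020	2	-2	FALSE
g0021	3	0	FALSE
g0022	3	0	FALSE
g0023	3	0	FALSE
g0024	3	0	FALSE
g0025	3	0	FALSE
g0026	3	0	FALSE
g0027	3	0	FALSE
g0028	3	0	FALSE
g0029	3	0	FALSE
g0030	3	0	FALSE
g0031	4	0	FALSE
g0032	4	0	FALSE
g0033	4	0	FALSE
g0034	4	0	FALSE
g0035	4	0	FALSE
g0036	4	0	FALSE
g0037	4	0	FALSE
g0038	4	0	FALSE
g0039	4	0	FALSE
g0040	4	0	FALSE
g0041	5	0	FALSE
g0042	5	0	FALSE
g0043	5	0	FALSE
g0044	5	0	FALSE
g0045	5	0	FALSE
g0046	5	0	FALSE
g0047	5	0	FALSE
g0048	5	0	FALSE
g0049	5	0	FALSE
g0050	5	0	FALSE
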