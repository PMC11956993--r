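gene1	gene2	score
g0001	g0002	999
g0001	g0003	999
g0001	g0004	999
g0001	g0005	999
g0001	g0006	999
g0001	g0007	999
g0001	g0008	999
g0001	g0009	999
g0001	g0010	999
g0001	g0047	450
g0002	g0003	999
g0002	g0004	999
g0002	g0005	999
g0002	g0006	999
g0002	g0007	999
g0002	g0008	999
g0002	g0009	999
g0002	g0010	999
g0002	g0021	450
g0003	g0004	999
g0003	g0005	999
g0003	g0006	999
g0003	g0007	999
g0003	g0008	999
g0003	g0009	999
g0003	g0010	999
g0003	g0033	450
g0004	g0005	999
g0004	g0006	999
g0004	g0007	999
g0004	g0008	999
g0004	g0009	999
g0004	g0010	999
g0004	g0045	450
g0005	g0006	999
g0005	g0007	999
g0005	g0008	999
g0005	g0009	999
g0005	g0010	999
g0005	g0012	450
g0006	g0007	999
g0006	g0008	999
g0006	g0009	999
g0006	g0010	999
g0007	g0008	999
g0007	g0009	999
g0007	g0010	999
g0007	g0028	450
g0008	g0009	999
g0008	g0010	999
g0009	g0010	999
g0011	g0012	999
g0011	g0013	999
g0011	g0014	999
g0011	g0015	999
g0011	g0016	999
g0011	g0017	999
g0011	g0018	999
g0011	g0019	999
g0011	g0020	999
g0011	g0048	450
g0012	g0013	999
g0012	g0014	999
g0012	g0015	999
g0012	g0016	999
g0012	g0017	999
g0012	g0018	999
g0012	g0019	999
g0012	g0020	999
g0013	g0014	999
g0013	g0015	999
g0013	g0016	999
g0013	g0017	999
g0013	g0018	999
g0013	g0019	999
g0013	g0020	999
g0014	g0015	999
g0014	g0016	999
g0014	g0017	999
g0014	g0018	999
g0014	g0019	999
g0014	g0020	999
g0015	g0016	999
g0015	g0017	999
g0015	g0018	999
g0015	g0019	999
g0015	g0020	999
g0015	g0021	450
g0016	g0017	999
g0016	g0018	999
g0016	g0019	999
g0016	g0020	999
g0017	g0018	999
g0017	g0019	999
g0017	g0020	999
g0017	g0024	450
g0017	g0028	450
g0018	g0019	999
g0018	g0020	999
g0019	g0020	999
g0021	g0022	999
g0021	g0023	999
g0021	g0024	999
g0021	g0025	999
g0021	g0026	999
g0021	g0027	999
g0021	g0028	999
g0021	g0029	999
g0021	g0030	999
g0022	g0023	999
g0022	g0024	999
g0022	g0025	999
g0022	g0026	999
g0022	g0027	999
g0022	g0028	999
g0022	g0029	999
g0022	g0030	999
g0023	g0024	999
g0023	g0025	999
g0023	g0026	999
g0023	g0027	999
g0023	g0028	999
g0023	g0029	999
g0023	g0030	999
g0024	g0025	999
g0024	g0026	999
g0024	g0027	999
g0024	g0028	999
g0024	g0029	999
g0024	g0030	999
g0025	g0026	999
g0025	g0027	999
g0025	g0028	999
g0025	g0029	999
g0025	g0030	999
g0026	g0027	999
g0026	g0028	999
g0026	g0029	999
g0026	g0030	999
g0027	g0028	999
g0027	g0029	999
g0027	g0030	999
g0028	g0029	999
g0028	g0030	999
g0029	g0030	999
g0031	g0032	999
g0031	g0033	999
g0031	g0034	999
g0031	g0035	999
g0031	g0036	999
g0031	g0037	999
g0031	g0038	999
g0031	g0039	999
g0031	g0040	999
g0032	g0033	999
g0032	g0034	999
g0032	g0035	999
g0032	g0036	999
g0032	g0037	999
g0032	g0038	999
g0032	g0039	999
g0032	g0040	999
g0033	g0034	999
g0033	g0035	999
g0033	g0036	999
g0033	g0037	999
g0033	g0038	999
g0033	g0039	999
g0033	g0040	999
g0034	g0035	999
g0034	g0036	999
g0034	g0037	999
g0034	g0038	999
g0034	g0039	999
g0034	g0040	999
g0035	g0036	999
g0035	g0037	999
g0035	g0038	999
g0035	g0039	999
g0035	g0040	999
g0036	g0037	999
g0036	g0038	999
g0036	g0039	999
g0036	g0040	999
g0037	g0038	999
g0037	g0039	999
g0037	g0040	999
g0038	g0039	999
g0038	g0040	999
g0039	g0040	999
g0039	g0050	450
g0041	g0042	999
g0041	g0043	999
g0041	g0044	999
g0041	g0045	999
g0041	g0046	999
g0041	g0047	999
g0041	g0048	999
g0041	g0049	999
g0041	g0050	999
g0042	g0043	999
g0042	g0044	999
g0042	g0045	999
g0042	g0046	999
g0042	g0047	999
g0042	g0048	999
g0042	g0049	999
g0042	g0050	999
g0043	g0044	999
g0043	g0045	999
g0043	g0046	999
g0043	g0047	999
g0043	g0048	999
g0043	g0049	999
g0043	g0050	999
g0044	g0045	999
g0044	g0046	999
g0044	g0047	999
g0044	g0048	999
g0044	g0049	999
g0044	g0050	999
g0045	g0046	999
g0045	g0047	999
g0045	g0048	999
g0045	g0049	999
g0045	g0050	999
g0046	g0047	999
g0046	g0048	999
g0046	g0049	999
g0046	g0050	999
g0047	g0048	999
g0047	g0049	999
g0047	g0050	999
g0048	g0049	999
g0048	g0050	999
g0049	g0050	999
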