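coupling_mode	k	cluster	p_value	mean_controls	sem_controls	direction	mean_meditators	sem_meditators	hedges_g
CM1	14	14	4.3e-04	0.019	0.0042	<	0.054	0.0102	1.118
CM1	15	15	6.1e-04	0.009	0.0026	<	0.038	0.0093	1.041
CM1	16	16	3.6e-03	0.013	0.0028	<	0.036	0.0087	0.879
CM1	17	17	2.2e-03	0.014	0.0030	<	0.039	0.0092	0.931
CM1	18	18	1.4e-03	0.012	0.0023	<	0.038	0.0099	0.914
CM1	19	19	4.1e-03	0.008	0.0023	<	0.034	0.0099	0.879
CM1	20	20	8.6e-03	0.009	0.0022	<	0.028	0.0081	0.797
CM2	10	10	4.8e-03	0.069	0.0077	<	0.111	0.0135	0.936
CM2	11	11	7.6e-03	0.060	0.0068	<	0.095	0.0119	0.866
CM2	12	12	6.0e-03	0.059	0.0070	<	0.097	0.0127	0.898
CM2	13	13	8.9e-03	0.060	0.0073	<	0.095	0.0121	0.857
CM2	20	19	4.6e-02	0.052	0.0059	<	0.075	0.0117	0.605
CM3	4	4	2.3e-02	0.150	0.0188	>	0.104	0.0110	0.687
CM3	5	5	2.1e-02	0.133	0.0168	>	0.090	0.0108	0.710
CM3	6	6	2.8e-02	0.116	0.0156	>	0.078	0.0096	0.660
specific	19	18	3.4e-02	0.026	0.0086	>	0.009	0.0020	0.579
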