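feature_id	lineage	sample0001	sample0002	sample0003	sample0004	sample0005	sample0006	sample0007	sample0008	sample0009	sample0010	sample0011	sample0012
otu00001	k__T1;p__T1;c__T1;o__T1	0.01866	0.034363	0.066132	0.030226	0.03332	0.022897	0.022884	0	0	0.008105	0.055935	0.007848
otu00002	k__T1;p__T2;c__T2;o__T2	0.034038	0.116	0.099112	0.004838	0.012116	0	0.01178	0.697745	0.025462	0.076734	0	0.030402
otu00003	k__T1;p__T2;c__T3;o__T3	0.009994	0.01099	0.018339	0	0.002603	0.019843	0.061057	0.230906	0.04641	0	0.011756	0.004154
otu00004	k__T1;p__T3;c__T4;o__T4	0.073448	0	0.652165	0.035714	0.02152	0.200363	0	0.023879	0.021516	0.234318	0.022591	0.090544
otu00005	k__T2;p__T4;c__T5;o__T5	0	0.000617	0	0.000158	0.037711	0.538429	0.000779	0	0.003727	0.640316	0.740271	0.001209
otu00006	k__T2;p__T5;c__T6;o__T6	0.030168	0.023017	0.036297	0.897002	0.034188	0.002909	0.26244	0.010285	0.053173	0.013835	0.114689	0.00077
otu00007	k__T2;p__T6;c__T7;o__T7	0.004982	0.714048	0.001253	0.005263	0.002996	0.020797	0.55056	0.000108	0.36761	0.015063	0.00317	0.000136
otu00008	k__T3;p__T7;c__T8;o__T8	0.210592	0.019261	0.11937	0.026308	0.834282	0.009837	0.024042	0	0.010252	0.001644	0.016181	0.861843
otu00009	k__T3;p__T8;c__T9;o__T9	0.009639	0.060397	0.007331	0.00049	0.01355	0.184925	0.028667	0.037078	0.003311	0	0.009891	0.003093
otu00010	k__T3;p__T9;c__T10;o__T10	0.608479	0.021307	0	0	0.007715	0	0.037791	0	0.468538	0.009985	0.025517	0
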