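sequence_id	v_call	j_call	junction_aa	v_identity	j_identity
A_IGKV1-5_001	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_002	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_003	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_004	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_005	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_006	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_007	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_008	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_009	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_010	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_011	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_012	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_013	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_014	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_015	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_016	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_017	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_018	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_019	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_020	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_021	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_022	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_023	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_024	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_025	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_026	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_027	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_028	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_029	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_030	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_031	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_032	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_033	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_034	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_035	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_036	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_037	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_038	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_039	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_040	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_041	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_042	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_043	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_044	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_045	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_046	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_047	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_048	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_049	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_050	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_051	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_052	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_053	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_054	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_055	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_056	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_057	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_058	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_059	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_060	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_061	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_062	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_063	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_064	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_065	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_066	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_067	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_068	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_069	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-5_070	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_001	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_002	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_003	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_004	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_005	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_006	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_007	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_008	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_009	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_010	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_011	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_012	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_013	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_014	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_015	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_016	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_017	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_018	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_019	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_020	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_021	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_022	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_023	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_024	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_025	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_026	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_027	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_028	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_029	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_030	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_031	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_032	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_033	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_034	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_035	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_036	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_037	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_038	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_039	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV1-39_040	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_001	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_002	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_003	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_004	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_005	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_006	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_007	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_008	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_009	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
A_IGKV3-20_010	IGKV3-20*01	IGKJ1*01	CQQYNSYSF	1	1
Am_IGKV1-5_001	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_002	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_003	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_004	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_005	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_006	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_007	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_008	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_009	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_010	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_011	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_012	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_013	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_014	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_015	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_016	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_017	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_018	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_019	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-5_020	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	0.97	1
Am_IGKV1-39_001	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_002	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_003	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_004	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_005	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_006	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_007	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_008	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_009	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
Am_IGKV1-39_010	IGKV1-39*01	IGKJ1*01	CQQYNSYSF	1	0.96
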