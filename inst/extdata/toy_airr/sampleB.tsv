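sequence_id	v_call	j_call	junction_aa	v_identity	j_identity
B_IGKV1-5_001	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_002	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_003	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_004	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_005	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_006	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_007	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_008	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_009	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_010	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_011	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_012	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_013	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_014	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_015	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_016	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_017	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_018	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_019	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_020	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_021	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_022	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_023	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_024	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_025	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_026	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_027	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_028	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_029	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_030	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_031	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_032	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_033	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_034	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_035	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_036	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_037	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_038	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_039	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_040	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_041	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_042	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_043	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_044	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_045	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_046	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_047	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_048	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_049	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_050	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_051	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_052	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_053	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_054	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_055	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_056	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_057	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_058	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_059	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_060	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_061	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_062	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_063	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_064	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_065	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_066	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_067	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_068	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_069	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_070	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_071	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_072	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_073	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_074	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_075	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_076	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_077	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_078	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_079	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_080	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_081	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_082	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_083	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_084	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_085	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_086	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_087	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_088	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_089	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_090	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_091	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_092	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_093	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_094	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_095	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_096	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_097	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_098	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
B_IGKV1-5_099	IGKV1-5*01	IGKJ1*01	CQQYNSYSF	1	1
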