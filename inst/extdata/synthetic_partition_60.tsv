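roi_label	network	hemisphere
roi_001	FPN	L
roi_002	FPN	L
roi_003	FPN	L
roi_004	FPN	L
roi_005	FPN	L
roi_006	FPN	R
roi_007	FPN	R
roi_008	FPN	R
roi_009	FPN	R
roi_010	FPN	R
roi_011	LM	L
roi_012	LM	L
roi_013	LM	L
roi_014	LM	L
roi_015	LM	L
roi_016	LM	R
roi_017	LM	R
roi_018	LM	R
roi_019	LM	R
roi_020	LM	R
roi_021	SAL	L
roi_022	SAL	L
roi_023	SAL	L
roi_024	SAL	L
roi_025	SAL	R
roi_026	SAL	R
roi_027	SAL	R
roi_028	SAL	R
roi_029	DAN	L
roi_030	DAN	L
roi_031	DAN	L
roi_032	DAN	L
roi_033	DAN	R
roi_034	DAN	R
roi_035	DAN	R
roi_036	DAN	R
roi_037	DMN	L
roi_038	DMN	L
roi_039	DMN	L
roi_040	DMN	L
roi_041	DMN	R
roi_042	DMN	R
roi_043	DMN	R
roi_044	DMN	R
roi_045	SMN	L
roi_046	SMN	L
roi_047	SMN	L
roi_048	SMN	L
roi_049	SMN	R
roi_050	SMN	R
roi_051	SMN	R
roi_052	SMN	R
roi_053	VN	L
roi_054	VN	L
roi_055	VN	L
roi_056	VN	L
roi_057	VN	R
roi_058	VN	R
roi_059	VN	R
roi_060	VN	R
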