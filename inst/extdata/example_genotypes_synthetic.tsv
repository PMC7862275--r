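cell	timepoint	TET2a	JAK2	TET2b	ASXL1	SRSF2	TP53	FLT3
T1_c001	T1	HET	HET	HET	HET	HET	HET	HET
T1_c002	T1	HET	HET	HOM	HOM	HET	WT	WT
T1_c003	T1	HET	HET	WT	WT	WT	WT	WT
T1_c004	T1	HET	WT	WT	WT	WT	WT	WT
T1_c005	T1	HET	WT	WT	NA	WT	WT	WT
T1_c006	T1	WT	WT	WT	NA	WT	WT	WT
T1_c007	T1	HOM	HET	HOM	WT	WT	WT	WT
T1_c008	T1	HET	WT	WT	WT	WT	WT	HET
T1_c009	T1	HET	HET	HET	HET	WT	WT	WT
T1_c010	T1	HET	HET	HET	WT	HET	NA	WT
T1_c011	T1	HET	WT	WT	WT	WT	WT	WT
T1_c012	T1	HET	HET	WT	WT	NA	WT	WT
T1_c013	T1	WT	WT	WT	WT	WT	WT	WT
T1_c014	T1	HET	WT	WT	WT	WT	WT	WT
T1_c015	T1	HET	HET	HET	HET	HOM	WT	WT
T1_c016	T1	HET	HET	WT	WT	WT	WT	WT
T1_c017	T1	HET	WT	WT	WT	NA	WT	WT
T1_c018	T1	HET	WT	WT	WT	WT	WT	WT
T1_c019	T1	HOM	WT	WT	WT	WT	WT	WT
T1_c020	T1	HET	HET	HET	HOM	WT	HET	WT
T2_c001	T2	HET	HET	HOM	WT	HET	HET	HET
T2_c002	T2	HET	HET	HET	HET	HET	HET	WT
T2_c003	T2	HOM	WT	WT	WT	WT	WT	WT
T2_c004	T2	HET	WT	HET	HET	WT	WT	NA
T2_c005	T2	HET	HET	HET	HET	HET	HOM	HET
T2_c006	T2	HET	HET	HET	HET	WT	WT	WT
T2_c007	T2	HET	WT	WT	WT	WT	WT	WT
T2_c008	T2	HET	HOM	HET	HET	HET	HET	WT
T2_c009	T2	HET	NA	HET	HOM	HET	HOM	HET
T2_c010	T2	WT	HET	HET	HOM	HET	HOM	HET
T2_c011	T2	HET	HET	WT	WT	WT	WT	WT
T2_c012	T2	HOM	HET	HET	HOM	WT	HET	WT
T2_c013	T2	WT	HOM	WT	WT	WT	WT	WT
T2_c014	T2	HET	HET	WT	WT	WT	WT	WT
T2_c015	T2	HET	WT	HET	WT	WT	WT	WT
T2_c016	T2	HET	HET	WT	HET	HET	HET	HET
T2_c017	T2	HET	HET	HET	HET	HET	HOM	NA
T2_c018	T2	HET	HET	HET	HOM	HET	HET	WT
T2_c019	T2	HET	HET	HET	HOM	HET	HET	HET
T2_c020	T2	HET	HET	HET	HET	HET	WT	WT
T3_c001	T3	HET	HOM	HET	WT	WT	WT	WT
T3_c002	T3	HET	WT	NA	HET	HET	HET	WT
T3_c003	T3	HET	HET	WT	WT	WT	WT	WT
T3_c004	T3	HET	HET	HET	HOM	WT	WT	WT
T3_c005	T3	HET	HET	HET	HET	HET	WT	WT
T3_c006	T3	HET	HET	HET	HET	HET	WT	WT
T3_c007	T3	WT	HET	HET	HET	HET	WT	WT
T3_c008	T3	WT	HET	WT	HET	HET	HOM	NA
T3_c009	T3	HET	WT	WT	WT	WT	WT	WT
T3_c010	T3	HET	HET	HET	HET	WT	WT	WT
T3_c011	T3	HET	HET	HET	HET	WT	WT	WT
T3_c012	T3	HOM	WT	WT	WT	NA	WT	WT
T3_c013	T3	HOM	HET	WT	WT	WT	WT	WT
T3_c014	T3	HET	HET	HET	HET	HOM	HET	HET
T3_c015	T3	HET	HET	HET	HET	WT	HET	WT
T3_c016	T3	WT	WT	WT	WT	WT	WT	WT
T3_c017	T3	HET	HET	WT	WT	WT	WT	WT
T3_c018	T3	HET	HET	HET	HOM	HET	WT	WT
T3_c019	T3	HET	HET	HET	HET	HET	HET	WT
T3_c020	T3	WT	HET	HET	HET	HET	HOM	HET
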