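colony	timepoint	call
T2_col001	T2	HET
T2_col002	T2	HET
T2_col003	T2	HET
T2_col004	T2	HET
T2_col005	T2	HET
T2_col006	T2	HET
T2_col007	T2	HET
T2_col008	T2	HET
T2_col009	T2	HET
T2_col010	T2	HET
T2_col011	T2	HET
T2_col012	T2	WT
T2_col013	T2	WT
T2_col014	T2	HET
T2_col015	T2	WT
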