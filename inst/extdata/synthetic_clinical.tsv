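PATIENT_ID	CLAUDIN_SUBTYPE
S001	Basal
S002	Basal
S003	Basal
S004	Basal
S005	Basal
S006	Basal
S007	Basal
S008	Basal
S009	Basal
S010	Basal
S011	Basal
S012	Basal
S013	LuminalA
S014	LuminalA
S015	LuminalA
S016	LuminalA
S017	LuminalA
S018	LuminalA
S019	LuminalA
S020	LuminalA
S021	LuminalA
S022	LuminalA
S023	LuminalA
S024	LuminalA
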