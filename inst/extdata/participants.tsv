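participant_id	group	age	analyzed_sessions
ASD-P1	ASD	16	1,2
ASD-P2	ASD	11	1,2
ASD-P3	ASD	8	2,4
ASD-P4	ASD	8	2,4
ASD-P5	ASD	6	3,4
ASD-P6	ASD	9	1,2
TD-P1	TD	11	2
TD-P2	TD	11	1
TD-P3	TD	11	3
TD-P4	TD	9	2
TD-P5	TD	6	1
TD-P6	TD	11	1
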