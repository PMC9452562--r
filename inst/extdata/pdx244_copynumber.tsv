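sample_id	gene	log_ratio
2R	RB1	-0.9
2R	CDKN2A	-4.2
15L	RB1	-0.9
15L	CDKN2A	-0.4
15R	RB1	-0.9
15R	CDKN2A	-4.2
16L	RB1	-0.9
16L	CDKN2A	-4.2
16R	RB1	-0.9
16R	CDKN2A	-4.2
17L	RB1	-0.9
17L	CDKN2A	-0.4
18R	RB1	-0.9
18R	CDKN2A	-4.2
19L	RB1	-1.5
19L	CDKN2A	-4.2
19R	RB1	-2.0
19R	CDKN2A	-4.2
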