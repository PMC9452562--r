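sample_id	gene	protein_change	consequence
16L	RB1	p.M695Nfs*26	
16R	RB1	p.K810*	
18R	RB1	p.X180_splice	
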