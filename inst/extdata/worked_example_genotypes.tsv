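patient_id	gene	alteration_class	coo_label
131	CD79B	nonsynonymous_mutation	unclassified
73	MCL1	sv	unclassified
29	BCL2	sv	unclassified
29	STAT3	sv	unclassified
29	EZH2	sv	unclassified
47	TLR2	sv	unclassified
47	PTEN	sv	unclassified
34	CARD11	sv	unclassified
34	MYC	cn_high_gain	unclassified
34	BCL2	cn_high_gain	unclassified
60	MEF2B	nonsynonymous_mutation	unclassified
60	TLR2	nonsynonymous_mutation	unclassified
85	EP300	sv	unclassified
85	BCL2	sv	unclassified
27	BCL2	sv	unclassified
27	MYC	sv	unclassified
27	EZH2	sv	unclassified
27	MEF2B	sv	unclassified
27	CREBBP	sv	unclassified
27	PTEN	nonsynonymous_mutation	unclassified
92	NFKBIE	cn_high_gain	unclassified
92	IRF4	sv	unclassified
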