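gene	component	role	edge_sign
CD79B	BCR	oncogene	activating
SYK	SYK	oncogene	activating
BTK	BTK	oncogene	activating
HRAS	RAF	oncogene	activating
KRAS	RAF	oncogene	activating
NRAS	RAF	oncogene	activating
CARD11	CBM	oncogene	activating
BCL10	CBM	oncogene	activating
MALT1	CBM	oncogene	activating
TNFAIP3	IKKc	tumor_suppressor	inhibiting
TLR2	TRAF6	oncogene	activating
MYD88	TRAF6	oncogene	activating
REL	NFkB	oncogene	activating
NFKBIE	NFkB	oncogene	inhibiting
IRF4	IRF4	oncogene	activating
STAT1	STAT	oncogene	activating
STAT3	STAT	oncogene	activating
STAT5	STAT	oncogene	activating
STAT6	STAT	oncogene	activating
PTEN	PI3K	tumor_suppressor	inhibiting
MEF2B	BCL6	oncogene	activating
IRF8	BCL6	oncogene	activating
CREBBP	BCL6	tumor_suppressor	inhibiting
EP300	BCL6	tumor_suppressor	inhibiting
EZH2	BLIMP1	oncogene	inhibiting
MYC	MYC	oncogene	activating
BCL2	BCL2	oncogene	activating
BCL2L1	BCL2	oncogene	activating
MCL1	BCL2	oncogene	activating
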