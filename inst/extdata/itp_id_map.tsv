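from	to
K2C1	KRT1
K2C1_HUMAN	KRT1
VTDB	GC
VTDB_HUMAN	GC
FIBB	FGB
FIBB_HUMAN	FGB
FIBG	FGG
FIBG_HUMAN	FGG
ZF69B	ZFP69B
ZF69B_HUMAN	ZFP69B
HPT	HP
HPT_HUMAN	HP
APOA1	APOA1
APOA1_HUMAN	APOA1
FBX5	FBXO5
FBX5_HUMAN	FBXO5
RET4	RBP4
RET4_HUMAN	RBP4
DYRK4	DYRK4
DYRK4_HUMAN	DYRK4
KLH25	KLHL25
KLH25_HUMAN	KLHL25
SCRIB	SCRIB
SCRIB_HUMAN	SCRIB
K1C27	KRT27
K1C27_HUMAN	KRT27
SEH1	SEH1L
SEH1_HUMAN	SEH1L
TRFE	TF
TRFE_HUMAN	TF
K1C10	KRT10
K1C10_HUMAN	KRT10
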