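module	gene
module1	ACTB
module1	CDC42
module1	RUNX2
module1	HSPA8
module1	PSMD2
module1	GFAP
module1	VAMP2
module1	MAPK8
module1	CAV1
module1	GNB1
module1	RBX1
module1	ITGA2B
module2	AKT1
module2	ALB
module2	BDNF
module2	CAV1
module2	CD4
module2	CDC42
module2	CDH1
module2	DLG4
module2	EGF
module2	EGFR
module2	FN1
module2	GAPDH
module2	INS
module2	ITGB1
module2	ACTB
module2	SRC
module2	TP53
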