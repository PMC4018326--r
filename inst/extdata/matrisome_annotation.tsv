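accession	gene	matrisome_category	blood_related
A1AT_HUMAN	SERPINA1	ECM_regulator	TRUE
ACTH_HUMAN	ACTG2	non_matrisome	FALSE
ADA15_HUMAN	ADAM15	ECM_regulator	FALSE
ADH1_YEAST	ADH1	non_matrisome	FALSE
ADH1B_HUMAN	ADH1B	non_matrisome	FALSE
ALBU_HUMAN	ALB	non_matrisome	TRUE
AMBP_HUMAN	AMBP	ECM_regulator	TRUE
ANXA1_HUMAN	ANXA1	ECM_affiliated	FALSE
ANXA2_HUMAN	ANXA2	ECM_affiliated	FALSE
ANXA5_HUMAN	ANXA5	ECM_affiliated	FALSE
APOA1_HUMAN	APOA1	non_matrisome	TRUE
ASPN_HUMAN	ASPN	proteoglycan	FALSE
ATS7_HUMAN	ADAMTS7	ECM_regulator	FALSE
BGH3_HUMAN	TGFBI	glycoprotein	TRUE
CHAD_HUMAN	CHAD	proteoglycan	FALSE
CILP1_HUMAN	CILP	glycoprotein	FALSE
CLUS_HUMAN	CLU	ECM_affiliated	TRUE
CO1A1_HUMAN	COL1A1	collagen	FALSE
CO1A2_HUMAN	COL1A2	collagen	FALSE
CO2A1_HUMAN	COL2A1	collagen	FALSE
CO3A1_HUMAN	COL3A1	collagen	FALSE
CO5A2_HUMAN	COL5A2	collagen	FALSE
CO6A1_HUMAN	COL6A1	collagen	FALSE
CO6A2_HUMAN	COL6A2	collagen	FALSE
CO6A3_HUMAN	COL6A3	collagen	FALSE
CO8A1_HUMAN	COL8A1	collagen	FALSE
CO8A2_HUMAN	COL8A2	collagen	FALSE
CO9_HUMAN	C9	non_matrisome	TRUE
COCA1_HUMAN	COL12A1	collagen	FALSE
COEA1_HUMAN	COL14A1	collagen	FALSE
COGA1_HUMAN	COL16A1	collagen	FALSE
COLA1_HUMAN	COL21A1	collagen	FALSE
COMP_HUMAN	COMP	glycoprotein	FALSE
CSPG2_HUMAN	VCAN	proteoglycan	FALSE
ELN_HUMAN	ELN	glycoprotein	FALSE
FBN1_HUMAN	FBN1	glycoprotein	FALSE
FINC_HUMAN	FN1	glycoprotein	TRUE
FMOD_HUMAN	FMOD	proteoglycan	FALSE
H4_HUMAN	HIST1H4A	non_matrisome	FALSE
HRG_HUMAN	HRG	ECM_regulator	TRUE
LUM_HUMAN	LUM	proteoglycan	FALSE
MIME_HUMAN	OGN	proteoglycan	FALSE
MMP10_HUMAN	MMP10	ECM_regulator	FALSE
MMP11_HUMAN	MMP11	ECM_regulator	FALSE
MMP3_HUMAN	MMP3	ECM_regulator	FALSE
MYOC_HUMAN	MYOC	non_matrisome	FALSE
PGBM_HUMAN	HSPG2	proteoglycan	FALSE
PGCA_HUMAN	ACAN	proteoglycan	FALSE
PGS1_HUMAN	BGN	proteoglycan	FALSE
PGS2_HUMAN	DCN	proteoglycan	FALSE
POSTN_HUMAN	POSTN	glycoprotein	FALSE
PRELP_HUMAN	PRELP	proteoglycan	FALSE
PRG4_HUMAN	PRG4	proteoglycan	FALSE
S10AA_HUMAN	S100A10	non_matrisome	FALSE
SAMP_HUMAN	APCS	non_matrisome	TRUE
TENA_HUMAN	TNC	glycoprotein	FALSE
TENX_HUMAN	TNXB	glycoprotein	FALSE
TIMP3_HUMAN	TIMP3	ECM_regulator	FALSE
TRFE_HUMAN	TF	non_matrisome	TRUE
TSP1_HUMAN	THBS1	glycoprotein	FALSE
TSP4_HUMAN	THBS4	glycoprotein	FALSE
TTHY_HUMAN	TTR	non_matrisome	TRUE
VIME_HUMAN	VIM	non_matrisome	FALSE
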