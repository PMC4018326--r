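accession	gene	description	matrisome_category	blood_related	conc_acl_fmol_ug	conc_pt_fmol_ug	sex_fc_acl	sex_fc_pt
CO1A1_HUMAN	COL1A1	Collagen alpha-1(I) chain	collagen	FALSE	2.432513	3.892021	-1.2	-1.2
CO1A2_HUMAN	COL1A2	Collagen alpha-2(I) chain	collagen	FALSE	1.380373	2.084363	-1.23	-1.12
CO3A1_HUMAN	COL3A1	Collagen alpha-1(III) chain	collagen	FALSE	1.946192	0.4745233	1	1
CO6A1_HUMAN	COL6A1	Collagen alpha-1(VI) chain	collagen	FALSE	0.08	0.06	1	1.41
CO6A2_HUMAN	COL6A2	Collagen alpha-2(VI) chain	collagen	FALSE	0.04	0.03	1	1
CO6A3_HUMAN	COL6A3	Collagen alpha-3(VI) chain	collagen	FALSE	0.24	0.12	1	1
FINC_HUMAN	FN1	Fibronectin	glycoprotein	TRUE	0.05269416	0.00878236	1	1
CO9_HUMAN	C9	Complement component C9	non_matrisome	TRUE	0.02685097	0.00476081	-4.56	1
HRG_HUMAN	HRG	Histidine-rich glycoprotein	ECM_regulator	TRUE	0.02356678	0.004971894	1	1
MIME_HUMAN	OGN	Mimecan	proteoglycan	FALSE	0.1261521	0.02841263	1	1.31
VIME_HUMAN	VIM	Vimentin	non_matrisome	FALSE	0.02570311	0.007281334	1	2.01
CLUS_HUMAN	CLU	Clusterin	ECM_affiliated	TRUE	0.03328679	0.009429687	1	1
TENX_HUMAN	TNXB	Tenascin-X	glycoprotein	FALSE	0.01823286	0.005315704	1	1
ASPN_HUMAN	ASPN	Asporin	proteoglycan	FALSE	0.09085823	0.02778539	1	1
BGH3_HUMAN	TGFBI	TGF-beta-induced protein ig-h3	glycoprotein	TRUE	0.0249704	0.008029066	1	1
PGS1_HUMAN	BGN	Biglycan	proteoglycan	FALSE	0.2162026	0.07065445	1	1
ANXA1_HUMAN	ANXA1	Annexin A1	ECM_affiliated	FALSE	0.01556355	0.005102803	1	1
ANXA5_HUMAN	ANXA5	Annexin A5	ECM_affiliated	FALSE	0.01666876	0.005519457	1	1
TENA_HUMAN	TNC	Tenascin C	glycoprotein	FALSE	0.005928222	0.001982683	1	1
ELN_HUMAN	ELN	Elastin	glycoprotein	FALSE	0.02174051	0.008593087	1	1
TSP4_HUMAN	THBS4	Thrombospondin-4	glycoprotein	FALSE	0.02283789	0.009283694	1	1
PRELP_HUMAN	PRELP	Prolargin	proteoglycan	FALSE	0.3032308	0.1232646	1	1
CILP1_HUMAN	CILP	Cartilage intermediate layer protein 1	glycoprotein	FALSE	0.0542793	0.02242946	1	1
PGBM_HUMAN	HSPG2	Basement membrane heparan sulfate proteoglycan	proteoglycan	FALSE	0.007692331	0.00331566	1	1
H4_HUMAN	HIST1H4A	Histone H4	non_matrisome	FALSE	0.0817166	0.03631849	1	1
LUM_HUMAN	LUM	Lumican	proteoglycan	FALSE	0.09714196	0.04692848	1	1.81
A1AT_HUMAN	SERPINA1	Alpha-1-antitrypsin	ECM_regulator	TRUE	0.01792292	0.0104203	1	1
COMP_HUMAN	COMP	Cartilage oligomeric matrix protein	glycoprotein	FALSE	0.05863569	0.03597281	1	1
FBN1_HUMAN	FBN1	Fibrillin-1	glycoprotein	FALSE	0.01030476	0.01669372	1	1
FMOD_HUMAN	FMOD	Fibromodulin	proteoglycan	FALSE	0.02785857	0.08134702	1	1
AMBP_HUMAN	AMBP	Protein AMBP	ECM_regulator	TRUE	0.07069049	0.2771067	1	1
COCA1_HUMAN	COL12A1	Collagen alpha-1(XII) chain	collagen	FALSE	0.004740641	0.02948678	1	1
PGS2_HUMAN	DCN	Decorin	proteoglycan	FALSE	0.1710449	0.1710449	-1.22	1
PRG4_HUMAN	PRG4	Proteoglycan 4 (lubricin)	proteoglycan	FALSE	0.01646524	0.01646524	1	1
CO2A1_HUMAN	COL2A1	Collagen alpha-1(II) chain	collagen	FALSE	0.0141619	0.0141619	1	1
TTHY_HUMAN	TTR	Transthyretin	non_matrisome	TRUE	0.04956304	0.04956304	1	1.83
MYOC_HUMAN	MYOC	Myocilin	non_matrisome	FALSE	0.008578072	0.008578072	3.88	1
ADH1B_HUMAN	ADH1B	Alcohol dehydrogenase 1B	non_matrisome	FALSE	0.007373138	0.007373138	-4.98	1
TIMP3_HUMAN	TIMP3	Metalloproteinase inhibitor 3	ECM_regulator	FALSE	0.02033604	0.02033604	1	1
POSTN_HUMAN	POSTN	Periostin	glycoprotein	FALSE	0.01067577	0.01067577	1	1
ACTH_HUMAN	ACTG2	Actin, gamma-enteric smooth muscle	non_matrisome	FALSE	0.01465632	0.01465632	1	1.76
ANXA2_HUMAN	ANXA2	Annexin A2	ECM_affiliated	FALSE	0.01012353	0.01012353	1	1.56
TSP1_HUMAN	THBS1	Thrombospondin-1	glycoprotein	FALSE	0.006148809	0.006148809	1	-2.04
ALBU_HUMAN	ALB	Serum albumin	non_matrisome	TRUE	0.150651	0.150651	2.24	2.48
CO5A2_HUMAN	COL5A2	Collagen alpha-2(V) chain	collagen	FALSE	0.06853747	0	1	1
COEA1_HUMAN	COL14A1	Collagen alpha-1(XIV) chain	collagen	FALSE	0.04361388	0	1	1
PGCA_HUMAN	ACAN	Aggrecan core protein	proteoglycan	FALSE	0.09881745	0	1	1
CSPG2_HUMAN	VCAN	Versican core protein	proteoglycan	FALSE	0.05483614	0	1	1
MMP10_HUMAN	MMP10	Stromelysin-2	ECM_regulator	FALSE	0.01210287	0	1	1
CO8A1_HUMAN	COL8A1	Collagen alpha-1(VIII) chain	collagen	FALSE	0	0.05963687	1	1
MMP3_HUMAN	MMP3	Stromelysin-1	ECM_regulator	FALSE	0	0.02597784	1	-2.14
S10AA_HUMAN	S100A10	Protein S100-A10	non_matrisome	FALSE	0	0.05392738	1	1
ADH1_YEAST	ADH1	Alcohol dehydrogenase 1 (yeast), spiked standard	non_matrisome	FALSE	0	0	1	1
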