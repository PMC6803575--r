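# P327 iAMP21-ERG probemix catalogue (synthetic reconstruction)
# 46 chromosome-21 target probes in centromere-to-telomere order plus 8
# off-chromosome reference probes used only for intra-sample normalization.
# Gene targets follow the published probemix gene set; per-gene probe
# multiplicity: RUNX1 x6, ERG/DYRK1A/ETS2 x5 each, all other genes x1.
# approx_start_mbp are approximate hg19-era megabase positions, used only
# for ordering and block-span reporting. Reference probe identities and
# all coordinates are synthetic approximations, not MRC-Holland data.
# name=P327	version=synthetic-1
probe_id	gene_symbol	cytoband	order_index	approx_start_mbp	is_runx1	is_reference
HSPA13_01	HSPA13	21q11.2	0	15.74	FALSE	FALSE
SAMSN1_01	SAMSN1	21q11.2	1	15.86	FALSE	FALSE
MIR99A_01	MIR99A	21q21.1	2	17.91	FALSE	FALSE
BTG3_01	BTG3	21q21.1	3	18.96	FALSE	FALSE
TMPRSS15_01	TMPRSS15	21q21.1	4	19.64	FALSE	FALSE
NCAM2_01	NCAM2	21q21.1	5	22.40	FALSE	FALSE
MIR155_01	MIR155	21q21.3	6	26.95	FALSE	FALSE
APP_01	APP	21q21.3	7	27.25	FALSE	FALSE
CYYR1_01	CYYR1	21q21.3	8	27.86	FALSE	FALSE
ADAMTS5_01	ADAMTS5	21q21.3	9	28.29	FALSE	FALSE
BACH1_01	BACH1	21q22.11	10	30.57	FALSE	FALSE
TIAM1_01	TIAM1	21q22.11	11	32.49	FALSE	FALSE
OLIG2_01	OLIG2	21q22.11	12	34.40	FALSE	FALSE
KCNE2_01	KCNE2	21q22.11	13	35.74	FALSE	FALSE
RUNX1_01	RUNX1	21q22.12	14	36.17	TRUE	FALSE
RUNX1_02	RUNX1	21q22.12	15	36.21	TRUE	FALSE
RUNX1_03	RUNX1	21q22.12	16	36.26	TRUE	FALSE
RUNX1_04	RUNX1	21q22.12	17	36.31	TRUE	FALSE
RUNX1_05	RUNX1	21q22.12	18	36.36	TRUE	FALSE
RUNX1_06	RUNX1	21q22.12	19	36.40	TRUE	FALSE
SIM2_01	SIM2	21q22.13	20	38.00	FALSE	FALSE
HLCS_01	HLCS	21q22.13	21	38.12	FALSE	FALSE
DYRK1A_01	DYRK1A	21q22.13	22	38.74	FALSE	FALSE
DYRK1A_02	DYRK1A	21q22.13	23	38.78	FALSE	FALSE
DYRK1A_03	DYRK1A	21q22.13	24	38.82	FALSE	FALSE
DYRK1A_04	DYRK1A	21q22.13	25	38.85	FALSE	FALSE
DYRK1A_05	DYRK1A	21q22.13	26	38.89	FALSE	FALSE
KCNJ6_01	KCNJ6	21q22.13	27	39.00	FALSE	FALSE
ERG_01	ERG	21q22.2	28	39.75	FALSE	FALSE
ERG_02	ERG	21q22.2	29	39.82	FALSE	FALSE
ERG_03	ERG	21q22.2	30	39.89	FALSE	FALSE
ERG_04	ERG	21q22.2	31	39.96	FALSE	FALSE
ERG_05	ERG	21q22.2	32	40.03	FALSE	FALSE
ETS2_01	ETS2	21q22.2	33	40.18	FALSE	FALSE
ETS2_02	ETS2	21q22.2	34	40.21	FALSE	FALSE
ETS2_03	ETS2	21q22.2	35	40.24	FALSE	FALSE
ETS2_04	ETS2	21q22.2	36	40.27	FALSE	FALSE
ETS2_05	ETS2	21q22.2	37	40.30	FALSE	FALSE
PSMG1_01	PSMG1	21q22.2	38	40.53	FALSE	FALSE
TMPRSS2_01	TMPRSS2	21q22.3	39	42.84	FALSE	FALSE
RIPK4_01	RIPK4	21q22.3	40	43.27	FALSE	FALSE
TFF1_01	TFF1	21q22.3	41	43.78	FALSE	FALSE
ITGB2_01	ITGB2	21q22.3	42	46.31	FALSE	FALSE
SLC19A1_01	SLC19A1	21q22.3	43	46.91	FALSE	FALSE
COL6A2_01	COL6A2	21q22.3	44	47.53	FALSE	FALSE
PRMT2_01	PRMT2	21q22.3	45	48.08	FALSE	FALSE
REF_01	REF	2p13.1	NA	NA	FALSE	TRUE
REF_02	REF	4q25	NA	NA	FALSE	TRUE
REF_03	REF	5q31.1	NA	NA	FALSE	TRUE
REF_04	REF	7p14.1	NA	NA	FALSE	TRUE
REF_05	REF	11q13.2	NA	NA	FALSE	TRUE
REF_06	REF	13q14.2	NA	NA	FALSE	TRUE
REF_07	REF	17q21.31	NA	NA	FALSE	TRUE
REF_08	REF	19p13.12	NA	NA	FALSE	TRUE
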