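gene	uniprot	gene_id	ir_coverage_pct	ir_hits	total_interfacing	af_failed
BNIP3	Q12983	664	77.049	47	60	0
ATG9B	Q674R7	285973	72.131	44	68	1
SIAH1	Q8IUQ4	6477	68.852	42	55	0
NIX	O60238	665	68.852	42	57	1
MTX2	O75431	10651	67.213	41	54	0
MITF	O75030	4286	65.574	40	59	0
RABGEF1	Q9UJ41	27342	65.574	40	50	0
JNK	P45983	5599	62.295	38	50	0
ARIH1	Q9Y4X5	25820	62.295	38	60	0
USP30	Q70CQ3	84749	55.738	34	57	0
BCL2L13	Q9BXK5	23786	55.738	34	78	1
TAX1BP1	Q86VP1	8887	50.820	31	42	0
TOMM7	Q9P0U1	54543	50.820	31	36	0
E2F1	Q01094	1869	49.180	30	55	0
MUL1	Q969V5	79594	49.180	30	62	0
AMBRA1	Q9C0C7	55626	24.590	15	55	0
SRC	P12931	6714	18.033	11	37	0
TFEB	P19484	7942	9.836	6	58	1
HIF1	Q16665	3091	8.197	5	51	0
PERK	Q9NZJ5	9451	6.557	4	63	0
OPTN	Q96CV9	10133	1.639	1	42	1
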