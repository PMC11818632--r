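gene	uniprot	gene_id	ir_coverage_pct	ir_hits	total_interfacing
CCZ1	P86790	221960	72.131	44	53
PINK1	Q9BXM7	65018	70.492	43	64
TBK1	Q9UHD2	29110	70.492	43	52
RAB7B	Q96AH8	338382	62.295	38	50
TOMM40	O96008	10452	57.377	35	50
TFE3	P19532	7030	57.377	35	78
MON1B	Q7L1V2	22879	57.377	35	56
CITED2	Q99967	10370	57.377	35	66
NLRX1	Q86UT6	79671	54.098	33	36
NDP52	Q13137	10241	50.820	31	57
NBR1	Q14596	4077	50.820	31	54
RABGEF1	Q9UJ41	27342	49.180	30	45
ATF4F	P18848	468	47.541	29	72
HIF1	Q16665	3091	44.262	27	66
USP15	Q9Y4E8	9958	44.262	27	52
SIAH1	Q8IUQ4	6477	42.623	26	62
ULK1	O75385	8408	40.984	25	58
BNIP3	Q12983	664	40.984	25	66
TAX1BP1	Q86VP1	8887	40.984	25	69
ARIH1	Q9Y4X5	25820	40.984	25	59
TOMM7	Q9P0U1	54543	39.344	24	44
AMBRA1	Q9C0C7	55626	37.705	23	49
MITF	O75030	4286	36.066	22	49
SRC	P12931	6714	36.066	22	50
TBC1D15	Q8TC07	64786	36.066	22	48
JNK	P45983	5599	22.951	14	57
E2F1	Q01094	1869	21.311	13	74
MUL1	Q969V5	79594	21.311	13	43
PERK	Q9NZJ5	9451	19.672	12	55
MTX2	O75431	10651	16.393	10	45
USP30	Q70CQ3	84749	14.754	9	69
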