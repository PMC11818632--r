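gene	uniprot	gene_id	delta_printed	expanded	wt
SAMM50	Q9Y512	25813	34.211	76	50
RAS	P62070	22800	31.148	61	42
TOMM7	Q9P0U1	54543	26.531	49	36
BCL-xL	Q07817	598	26.389	72	53
GP78	Q9UKV5	267	25.000	68	51
Parkin	O60260	5071	22.222	63	49
FOXO3	O43524	2309	21.154	52	41
USP30	Q70CQ3	84749	18.57	70	57
MITF	O75030	4286	18.056	72	59
C-JUN	P05412	3725	15.789	76	64
MARCHF5	Q9NX47	54708	15.714	70	59
FIS1	Q9Y3D6	51024	15.686	51	43
TOMM40	O96008	10452	15.254	59	50
Beclin1	Q14457	8678	15.152	66	56
ARIH1	Q9Y4X5	25820	11.765	68	60
FUNDC1	Q8IVP5	139341	8.475	59	54
SIAH1	Q8IUQ4	6477	8.333	60	55
NDP52	Q13137	10241	8.065	62	57
P53	P04637	7157	7.692	65	60
TOMM70	O94826	9868	5.660	53	50
VCP	P55072	7415	5.634	71	67
TAX1BP1	Q86VP1	8887	5.556	54	51
ATG9B	Q674R7	285973	5.556	72	68
NBR1	Q14596	4077	5.263	57	54
PGAM5	Q96HS1	192111	3.333	60	58
MON1B	Q7L1V2	22879	1.754	57	56
CK2	P68400	1457	1.667	60	59
SP1	P08047	6667	0.000	62	62
JNK	P45983	5599	0.000	50	50
CITED2	Q99967	10370	-1.538	65	66
PHB2	Q99623	11331	-1.786	56	57
TOMM20L	Q6UXN7	387990	-2.128	47	48
RABGEF1	Q9UJ41	27342	-4.167	48	50
NLRX1	Q86UT6	79671	-9.091	33	36
UBC	P62979	6233	-11.628	43	48
BNIP3	Q12983	664	-13.208	53	60
RAB7B	Q96AH8	338382	-13.636	44	50
MTX2	O75431	10651	-14.894	47	54
CCZ1	P86790	221960	-17.778	45	53
PINK1	Q9BXM7	65018	-25.490	51	64
BCL2L13	Q9BXK5	23786	-25.806	62	78
MFN2	O95140	9927	-27.083	48	61
NIX	O60238	665	-32.558	43	57
TFE3	P19532	7030	-36.842	57	78
TBK1	Q9UHD2	29110	-40.541	37	52
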