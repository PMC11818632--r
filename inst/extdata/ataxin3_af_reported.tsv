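gene	uniprot	gene_id	ir_coverage_pct	ir_hits	total_interfacing
MARCHF5	Q9NX47	54708	72.131	44	59
MFN2	O95140	9927	70.492	43	61
VCP	P55072	7415	67.213	41	67
FUNDC1	Q8IVP5	139341	67.213	41	54
Parkin	O60260	5071	65.574	40	49
RAS	P62070	22800	60.656	37	42
TOMM70	O94826	9868	55.738	34	50
SP1	P08047	6667	55.738	34	62
CK2	P68400	1457	54.098	33	59
PGAM5	Q96HS1	192111	54.098	33	58
P53	P04637	7157	52.459	32	60
Beclin1	Q14457	8678	52.459	32	56
GP78	Q9UKV5	267	52.459	32	51
SAMM50	Q9Y512	25813	52.459	32	50
UBC	P62979	6233	49.180	30	35
TOMM20L	Q6UXN7	387990	47.541	29	35
LC3	O95166	11337	45.902	28	38
BCL-xL	Q07817	598	45.902	28	75
USP8	P40818	9101	42.623	26	59
SMURF1	Q9HCE7	57154	37.705	23	54
p62	Q13501	8878	36.066	22	70
OPA1	O60313	4976	34.426	21	47
FOXO3	O43524	2309	26.230	16	57
EIF-2A	P05198	1965	26.223	16	44
PHB2	Q99623	11331	14.754	9	49
FIS1	Q9Y3D6	51024	13.115	8	45
RAB5A	P20339	5868	11.475	7	50
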