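gene	uniprot	gene_id	ir_coverage_pct	ir_hits	total_interfacing	af_failed
FIS1	Q9Y3D6	51024	63.934	39	43	0
PHB2	Q99623	11331	60.656	37	57	0
UBC	P62979	6233	57.377	35	48	0
FOXO3	O43524	2309	55.738	34	41	0
TOMM20L	Q6UXN7	387990	52.459	32	48	0
C-JUN	P05412	3725	52.459	32	64	1
BCL-xL	Q07817	598	50.820	31	53	0
EIF-2A	P05198	1965	49.180	30	54	0
p62	Q13501	8878	49.180	30	42	0
LC3	O95166	11337	45.902	28	39	0
FKBP8	Q14318	23770	45.902	28	56	1
OPA1	O60313	4976	44.262	27	57	0
NFKB	Q04206	5970	42.623	26	61	1
TRAF2	Q12933	7186	36.066	22	46	1
USP8	P40818	9101	26.230	16	38	0
SMURF1	Q9HCE7	8878	18.033	11	31	0
RAB5A	P20339	5868	16.393	10	43	0
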