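gene	uniprot	gene_id	source
HUWE1	Q7Z6Z7	10075	AF
HUWE1	Q7Z6Z7	10075	DIT
ULK1	O75385	8408	DIT
ATF4F	P18848	468	DIT
USP15	Q9Y4E8	9958	DIT
TBC1D15	Q8TC07	64786	DIT
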