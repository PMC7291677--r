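symbol	uniprot	entrez
ATP13A2	Q9NQ11	23400
FBXO7	Q9Y3I1	25793
GBA	P04062	2629
PINK1	Q9BXM7	65018
SMPD1	P17405	6609
VPS35	Q96QK1	55737
SNCA	P37840	6622
PRKN	O60260	5071
LRRK2	Q5S007	120892
CYCS	P99999	54205
TP53	P04637	7157
EGFR	P00533	1956
AKT1	P31749	207
MAPT	P10636	4137
APP	P05067	351
SOD1	P00441	6647
HTT	P42858	3064
FUS	P35637	2521
TARDBP	Q13148	23435
UBC	P0CG48	7316
HSPA8	P11142	3312
YWHAE	P62258	7531
GAK	O14976	2580
DNAJC6	O75061	9829
SYT11	Q9BT88	23208
RAB7A	P51149	7879
VPS26A	O75436	9559
VPS29	Q9UBQ0	51699
TOM1L2	Q6ZVM7	146691
CHMP4B	Q9H444	128866
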