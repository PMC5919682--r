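gene	chrom	pos	ref	alt	transcript	cdna	protein	dbsnp	patient_id	criteria	acmg_auto	acmg_manual	ihc_retained
ATM	11	108117784	A	G	NM_000051.3	c.995A>G	p.(Tyr332Cys)	.	HPC238	A1,A2,A3	PM2;BP1	.	.
ATM	11	108121787	G	A	NM_000051.3	c.1595G>A	p.(Cys532Tyr)	rs35963548	HPC167	B2	PM2;PP3;BP1	.	.
ATM	11	108121787	G	A	NM_000051.3	c.1595G>A	p.(Cys532Tyr)	rs35963548	HPC400	B1	PM2;PP3;BP1	.	.
ATM	11	108178699	G	A	NM_000051.3	c.5750G>A	p.(Arg1917Lys)	.	HPC20	B1	PM2;PP3;BP1	.	.
ATM	11	108216611	C	T	NM_000051.3	c.8560C>T	p.(Arg2854Cys)	rs201958469	HPC3	A3	PM1;PM2;PP3;BP1	PS4	.
ATM	11	108216611	C	T	NM_000051.3	c.8560C>T	p.(Arg2854Cys)	rs201958469	HPC186	B1,B2	PM1;PM2;PP3;BP1	PS4	.
ATM	11	108216611	C	T	NM_000051.3	c.8560C>T	p.(Arg2854Cys)	rs201958469	HPC332	A3,B1	PM1;PM2;PP3;BP1	PS4	.
BRIP1	17	59885899	T	C	NM_032043.2	c.847T>C	p.(Cys283Arg)	.	HPC118	A2	PM2;PP3;BP1	.	.
CHEK2	22	29121326	A	G	NM_007194.3	c.349A>G	p.(Arg117Gly)	rs28909982	HPC188	A1,A2	PM2;PP3;PP5	PS3	.
CHEK2	22	29121326	A	G	NM_007194.3	c.349A>G	p.(Arg117Gly)	rs28909982	HPC289	B1,B3	PM2;PP3;PP5	PS3	.
CHEK2	22	29107994	G	T	NM_007194.3	c.695G>T	p.(Gly232Val)	rs779322187	HPC89	B2	PM1;PM2;PP3	.	.
MSH2	2	47693857	G	A	NM_000251.2	c.1571G>A	p.(Arg524His)	rs63751207	HPC371	B3	.	.	yes
MSH6	2	48026851	C	T	NM_000179.2	c.1729C>T	p.(Arg577Cys)	rs542838372	HPC332	A3,B1	.	.	yes
TP53	17	7577099	G	A	NM_000546.5	c.839G>A	p.(Arg280Lys)	.	HPC394	A1,A2,B2	PM2;PP3	.	.
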