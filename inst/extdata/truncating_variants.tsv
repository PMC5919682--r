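gene	chrom	pos	ref	alt	transcript	cdna	protein	dbsnp	patient_id	criteria	consequence	intron_distance
ATM	11	108114835	C	T	NM_000051.3	c.652C>T	p.(Gln218Ter)	.	HPC177	A1,A2	nonsense	0
CHEK2	22	29115474	G	T	NM_007194.3	c.593-1G>T	p.(?)	rs786203229	HPC395	B3	splice_site	1
FANCD2	3	10109003	T	C	NM_001018115.1	c.2494+2T>C	p.(?)	rs779552164	HPC447	B3	splice_site	2
FANCI	15	89803992	CT	C	NM_001113378.1	c.206del	p.(Tyr69SerfsTer17)	.	HPC150	A2	frameshift	0
RAD51C	17	56798156	GACTGACTGAC	G	NM_058216.2	c.890_899del	p.(Leu297HisfsTer2)	.	HPC186	B1,B2	frameshift	0
CEP57	11	95555126	C	G	NM_014679.4	c.791C>G	p.(Ser264Ter)	rs368470481	HPC421	B2	nonsense	0
RECQL4	8	145738349	GC	G	NM_004260.3	c.2636del	p.(Pro879LeufsTer69)	.	HPC455	B2	frameshift	0
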