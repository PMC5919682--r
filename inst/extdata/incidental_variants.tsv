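gene	chrom	pos	ref	alt	transcript	cdna	protein	dbsnp	patient_id	criteria	consequence	intron_distance
MSH6	2	48033700	GACTGACTGACTGACT	G	NM_000179.2	c.3846_3860del	.	.	HPC186	B1,B2	inframe_indel	0
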