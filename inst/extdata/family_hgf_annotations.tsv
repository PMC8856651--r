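chrom	pos	ref	alt	gene	region_class	hgvs_c	af_exac	af_1000g	af_gnomad
chr7	149832310	G	A	ZNF862	exon	c.2812G>A	0	0	0
chr13	51937284	G	A	ATP7B	exon	c.3403G>A	0.0001	0	0.0002
chr13	49793000	G	T	CDADC1	splice_site	c.83-13G>T	0	0	0.0001
chr2	39100000	T	C	SOS1	intron	c.1310-55T>C	0.11	0.09	0.12
chr2	39250000	C	T		utr
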