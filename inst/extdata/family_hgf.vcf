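##fileformat=VCFv4.2
##source=famseg_fixture (reconstructed family genotypes: causal variant het in all 12 affected genotyped members, hom-ref in all 11 unaffected; two decoy variants co-segregating only in the 10-member WES subset; two background variants)
##contig=<ID=chr7>
##contig=<ID=chr13>
##contig=<ID=chr2>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	II-1	II-2	II-3	II-4	II-5	II-6	II-7	II-8	II-9	III-1	III-2	III-3	III-4	III-5	III-6	III-7	III-8	III-9	IV-1	IV-2	IV-3	IV-4	IV-5
chr7	149832310	.	G	A	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1
chr13	51937284	.	G	A	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1
chr13	49793000	.	G	T	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1
chr2	39100000	.	T	C	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0
chr2	39250000	.	C	T	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
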