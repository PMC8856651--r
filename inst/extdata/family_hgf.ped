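# Four-generation autosomal-dominant gingival fibromatosis family,
# reconstructed topology. Genotyped members, sexes and affection statuses
# follow the published clinical table (12 heterozygous carriers, all
# affected; 11 wild-type, all unaffected); the two generation-I founders
# are deceased and ungenotyped, with the affected founder an obligate
# carrier. The exact sibling-vs-spouse assignment within generations II-III
# is not recoverable from text, so this file fixes one structure consistent
# with those constraints and with 12 phase-known informative meioses:
# III-3 and III-6 are carrier first cousins whose child IV-5 has two
# carrier parents (phase unresolvable, meiosis excluded from LOD scoring),
# II-5 x II-6 are a married-in couple (parents of III-1 and III-9), and
# II-9 is a married-in relative with no offspring listed.
# Columns: family id father mother sex(1=M,2=F) phenotype(2=aff,1=unaff)
HGF1	I-1	0	0	1	2
HGF1	I-2	0	0	2	1
HGF1	II-1	0	0	1	1
HGF1	II-2	I-1	I-2	2	2
HGF1	II-3	I-1	I-2	1	2
HGF1	II-4	0	0	2	1
HGF1	II-5	0	0	1	1
HGF1	II-6	0	0	2	1
HGF1	II-7	0	0	1	1
HGF1	II-8	I-1	I-2	2	2
HGF1	II-9	0	0	2	1
HGF1	III-1	II-5	II-6	2	1
HGF1	III-2	II-1	II-2	1	2
HGF1	III-3	II-1	II-2	2	2
HGF1	III-4	II-3	II-4	1	2
HGF1	III-5	0	0	2	1
HGF1	III-6	II-7	II-8	1	2
HGF1	III-7	II-7	II-8	2	2
HGF1	III-8	0	0	2	1
HGF1	III-9	II-5	II-6	1	1
HGF1	IV-1	III-2	III-1	1	2
HGF1	IV-2	III-2	III-1	2	2
HGF1	IV-3	III-4	III-5	2	2
HGF1	IV-4	III-4	III-5	2	1
HGF1	IV-5	III-6	III-3	1	2
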