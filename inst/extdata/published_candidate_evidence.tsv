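gene	gene_context	normal_expression	tumor_fraction	cell_fraction	restore_fraction
DPP6	exon1	expressed	8/11	14/14	1/3
DDX25	exon1	very_low	-	-	-
ZNF577	exon1	expressed	6/11	10/14	0/3
FEZF2	gene_body	very_low	-	-	-
PEAR1	exon1	expressed	5/11	14/14	0/3
MEIS2	gene_body	expressed	4/11	3/14	1/3
TRIM58	exon1	expressed	10/11 (36/37)	10/14	3/3
C12orf42	gene_body	very_low	-	-	-
PTPRN2	gene_body	expressed	3/11	7/14	2/3
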