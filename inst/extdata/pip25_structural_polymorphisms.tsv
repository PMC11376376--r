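accession	pip25_expression_mz	lead_snp_dosage	mite_indel	intron_indel	large_indel	splice_variant	source
PHK76	-5.31	0	+	+	-	+	man
NC358	-5.16	0	+	-	-	+	man
MS71	-4.66	0	+	+	-	+	ref
F894	-4.39	0	+	+	-	+	man
PH207	-3.89	0	+	+	-	+	ref/man
Mo17	-3.51	0	+	+	-	+	ref
B100	-1.59	0	-	-	-	+	man
A374	-1.45	0	+	+	-	+	man
B97	-1.20	1	+	+	-	+	ref
EP52	-1.26	2	-	+	+	+	man
F98902	-0.39	2	-	-	+	-	man
B104	0.24	2	-	-	+	-	ref/man
Oh43	0.43	2	-	-	partial	+	ref/man
B73	0.70	2	-	-	+	-	ref
UH007	NA	2	-	-	partial	NA	man
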