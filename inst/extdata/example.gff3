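##gff-version 3
chr2	example	gene	6	28	.	+	.	ID=geneA
chr2	example	mRNA	6	28	.	+	.	ID=geneA.t1;Parent=geneA
chr2	example	CDS	6	14	.	+	0	ID=geneA.c1;Parent=geneA.t1
chr2	example	CDS	20	28	.	+	0	ID=geneA.c2;Parent=geneA.t1
chr2	example	gene	35	52	.	-	.	ID=geneB
chr2	example	mRNA	35	52	.	-	.	ID=geneB.t1;Parent=geneB
chr2	example	CDS	35	52	.	-	0	ID=geneB.c1;Parent=geneB.t1
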