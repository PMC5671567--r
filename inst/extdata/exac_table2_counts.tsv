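# Published worked-example genotype counts: three variants x six super-populations.
# Genotype counts are the printed values. Allele A is the table's printed A allele.
# chrom/pos/ref/alt are NOT printed in the source table: positions are placeholders
# (rs7551421 placed inside the deletion polymorphism esv3587138, whose coordinates
# are published); rs58896934 is an indel, given length-discrepant placeholder alleles.
# n_missing = super-population size (AFR 5302, AMR 5789, EAS 4327, FIN 3307,
# NFE 33370, SAS 8256) minus called genotypes.
variant_id	chrom	pos	ref	alt	population	n_aa	n_ab	n_bb	n_missing
rs7551421	1	108826000	A	G	AFR	691	2455	2051	105
rs7551421	1	108826000	A	G	EAS	2392	1463	429	43
rs7551421	1	108826000	A	G	FIN	864	1630	812	1
rs7551421	1	108826000	A	G	NFE	5564	15393	12372	41
rs7551421	1	108826000	A	G	AMR	1658	2593	1523	15
rs7551421	1	108826000	A	G	SAS	2149	3760	2333	14
rs509360	11	61781087	A	G	AFR	3552	1468	173	109
rs509360	11	61781087	A	G	EAS	968	1914	1434	11
rs509360	11	61781087	A	G	FIN	416	1503	1380	8
rs509360	11	61781087	A	G	NFE	3423	14518	15378	51
rs509360	11	61781087	A	G	AMR	195	1396	4190	8
rs509360	11	61781087	A	G	SAS	4205	3292	749	10
rs58896934	1	190000000	AT	A	AFR	110	1620	2198	1374
rs58896934	1	190000000	AT	A	EAS	829	2124	622	752
rs58896934	1	190000000	AT	A	FIN	917	1632	416	342
rs58896934	1	190000000	AT	A	NFE	5685	16989	4949	5747
rs58896934	1	190000000	AT	A	AMR	531	2895	1412	951
rs58896934	1	190000000	AT	A	SAS	1943	4079	941	1293
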