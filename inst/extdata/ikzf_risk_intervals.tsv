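name	locus	chrom	start	end	reference	description
ikzf3_extended	IKZF3	chr17	37879762	38074046		Extended European risk haplotype (ERBB2 intron 19 to upstream of ORMDL3), 282 tag-SNPs
ikzf3_1000g	IKZF3	chr17	37916823	38023745	ikzf3_extended	Shared block after 1000 Genomes AFR/EUR/AMR alignment, 152 tag-SNPs
ikzf3_core	IKZF3	chr17	37920146	38021117	ikzf3_extended	Final core risk haplotype after African-American ImmunoChip refinement, 140 tag-SNPs
ikzf1_gwas	IKZF1	chr7	50258234	50318308		European GWAS risk haplotype upstream of IKZF1, 186 tag-SNPs
ikzf1_asn	IKZF1	chr7	50258479	50324037		Chinese GWAS risk haplotype, 198 tag-SNPs
ikzf1_core	IKZF1	chr7	50271064	50308811	ikzf1_gwas	Trans-ancestrally refined core around rs4917014, 15 tag-SNPs
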