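#!/usr/bin/env Rscript
# Stage 3: per-ancestry association, meta-analysis, exclusion mapping.
#
# Tests every discovery tag-SNP allelically in both ancestries, pools
# the two with fixed (inverse-variance) and random (DerSimonian-Laird)
# effects, and classifies each tag by the trans-ancestral exclusion
# rules: Group 1 = rare in the replication ancestry yet still compatible
# with the discovery effect (candidate causal tags); Group 2 = commoner
# in replication but null there (alleles riding other backgrounds,
# excluded).

suppressMessages(library(texmap))

data_dir <- "results/data"
out <- "results"
pheno <- read_phenotypes(file.path(data_dir, "phenotypes.tsv"))
index <- "v0030"

eur <- read_panel_vcf(file.path(data_dir, "eur.vcf"), "EUR", pheno)
aa <- read_panel_vcf(file.path(data_dir, "aa.vcf"), "AA", pheno)
tags <- read.table(file.path(out, "tags_EUR.tsv"), header = TRUE,
                   stringsAsFactors = FALSE)$id

assoc_eur <- allelic_association(subset_panel(eur, tags), "EUR")
assoc_aa <- allelic_association(subset_panel(aa, tags), "AA")
meta <- meta_analyze(rbind(assoc_eur, assoc_aa))
groups <- exclusion_mapping(tags, assoc_eur, assoc_aa, meta,
                            rules = list(index_variant = index))

write.table(assoc_eur, file.path(out, "association_EUR.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(assoc_aa, file.path(out, "association_AA.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(meta, file.path(out, "meta.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(groups, file.path(out, "exclusion_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ix <- assoc_eur[assoc_eur$id == index, ]
cat(sprintf(
  "Index %s discovery association: OR %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
  index, ix$or, ix$ci_lo, ix$ci_hi, ix$p))
tab <- table(groups$group)
cat(sprintf("Exclusion mapping over %d tags: %s\n", nrow(groups),
            paste(sprintf("%s = %d", names(tab), as.integer(tab)),
                  collapse = ", ")))
g2 <- groups[groups$group == "Group2", ]
if (nrow(g2)) {
  cat(sprintf(
    "Group 2 tags average replication MAF %.2f vs discovery %.2f with I2 > 50 throughout.\n",
    mean(g2$maf_rep), mean(g2$maf_disc)))
}
g1 <- groups[groups$group == "Group1", ]
if (nrow(g1)) {
  cat(sprintf(
    "Group 1 tags are rare in replication (mean MAF %.4f) yet keep OR_rep compatible with discovery (mean %.2f).\n",
    mean(g1$maf_rep), mean(g1$or_rep)))
}
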