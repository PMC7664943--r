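#!/usr/bin/env Rscript
# Stage 1: generate the study panels and annotation fixtures.
#
# Three ancestries genotyped over one locus, mirroring the roles the
# real datasets play in trans-ancestral refinement:
#   EUR - discovery: its risk haplotype extends well beyond the shared
#         ancestral core, with the extra tag-SNPs riding it in perfect LD;
#   AFR - refinement panel: carries the core haplotype at a usable
#         frequency (12%) but its block stops at the conserved core;
#   AA  - replication cohort: the core haplotype is very rare (0.6%),
#         while the discovery-only tag alleles are common old alleles on
#         unrelated backgrounds (the exclusion-mapping contrast).
# One core variant is causal (allelic OR 2). Three core variants are
# designated functional and receive planted open-chromatin, interaction
# and motif signal. Everything downstream (02-04) reads only the files
# written here.

suppressMessages(library(texmap))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1109L

sim <- sim_config(
  n_variants = 60, core_span = c(21, 41), index_variant = 30,
  populations = list(
    pop_spec("EUR", 1000, 0.20, flank_extension = 6, risk_span = c(13, 49)),
    pop_spec("AFR", 1000, 0.12, flank_extension = 2, bg_logit_shift = 0.8),
    pop_spec("AA", 2000, 0.006, bg_logit_shift = 0.8)
  ),
  causal_variant = 30, causal_or = 2, case_fraction = 0.5,
  functional_set = c(24, 30, 37), seed = seed
)
panels <- simulate_panel(sim)
panels <- lapply(panels, assign_phenotypes, causal_variant = 30,
                 causal_or = 2, case_fraction = 0.5, seed = seed)
fx <- generate_tracks(panels$EUR, c(24, 30, 37), seed = seed)

ids <- lapply(panels, function(p) sprintf("%s%05d", substr(p$population[1], 1, 1),
                                          seq_len(n_samples(p))))
for (pop in names(panels)) {
  write_panel_vcf(panels[[pop]], file.path(out, paste0(tolower(pop), ".vcf")),
                  sample_ids = ids[[pop]])
}
pheno <- do.call(rbind, lapply(names(panels), function(pop) {
  data.frame(sample = ids[[pop]], population = pop,
             status = panels[[pop]]$phenotype)
}))
write.table(pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_track_bed(fx$tracks$dnase, file.path(out, "dnase_hotspots.bed"))
write_track_bed(fx$tracks$histone, file.path(out, "histone_25bp.bed"))
write_track_bed(fx$tracks$interaction, file.path(out, "pchic_fragments.bed"))
write_ref_fasta(fx$refseq, file.path(out, "locus.fa"))
write_meme(fx$pwms, file.path(out, "motifs.meme"))

cat(sprintf(
  "Simulated %d variants x {%s} under seed %d.\n",
  sim$n_variants,
  paste(sprintf("%s: %d samples", names(panels),
                vapply(panels, n_samples, integer(1))), collapse = ", "),
  seed))
cat(paste0(
  "Planted truth: core variants 21-40 (index/causal v0030, OR 2),\n",
  "  discovery-only tags 13-20 and 41-48, functional set {v0024, v0030, v0037}.\n"))
cat(sprintf("Wrote VCF/TSV/BED/FASTA/MEME inputs under %s\n", out))
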