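#!/usr/bin/env Rscript
# Stage 5: span arithmetic on the published IKZF1/IKZF3 risk-haplotype
# boundaries (hg19) and on the simulated core from stage 4.
#
# The published refinements: at IKZF3 the 194 kb extended European
# haplotype narrows to a 107 kb 1000G-refined block and a 101 kb final
# core (>44% and >47% reductions); at IKZF1 the 60 kb GWAS haplotype
# narrows to a 37,747 bp core (reported as 47.7 kb in one place and
# 37.7 kb in another; the boundary arithmetic gives 37.7 kb).

suppressMessages(library(texmap))

intervals <- read.table(
  system.file("extdata", "ikzf_risk_intervals.tsv", package = "texmap"),
  header = TRUE, sep = "\t", stringsAsFactors = FALSE
)

rows <- lapply(seq_len(nrow(intervals)), function(i) {
  iv <- intervals[i, ]
  ref <- if (nzchar(iv$reference) && !is.na(iv$reference)) {
    r <- intervals[intervals$name == iv$reference, ]
    c(r$start, r$end)
  }
  s <- span_report(iv$chrom, iv$start, iv$end, kb_precision = 1,
                   reference = ref)
  data.frame(name = iv$name, locus = iv$locus,
             interval = sprintf("%s:%d-%d", iv$chrom, iv$start, iv$end),
             span_bp = s$span_bp, span_kb = s$span_kb,
             reduction_pct = if (is.null(ref)) NA_real_
                             else round(s$reduction_pct, 1))
})
spans <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(spans, "results/spans.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(spans, row.names = FALSE)

pr <- try(read.table("results/priority.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE), silent = TRUE)
if (!inherits(pr, "try-error")) {
  core <- range(pr$pos)
  cat(sprintf("\nSimulated shared core spans %d bp across %d tags.\n",
              diff(core), nrow(pr)))
}
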