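---
title: "Trans-ancestral exclusion mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ancestral exclusion mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texmap)
```

## The problem

A genome-wide association signal for a common disease usually arrives as an
*extended risk haplotype*: tens to hundreds of variants in tight LD with the
index SNP, any one of which could be the functional allele. `texmap`
implements a two-pronged refinement of such a signal, as applied to the
*IKZF1* and *IKZF3* susceptibility loci in systemic lupus erythematosus:

1. **Trans-ancestral refinement.** Haplotype blocks differ in extent between
   ancestries because recombination and drift have had independent histories.
   Aligning each ancestry's block around the index variant and intersecting
   them yields the *core* haplotype conserved across ancestries — the segment
   most likely to carry the causal allele. A second, sharper filter
   (*exclusion mapping*) removes individual tag-SNPs whose frequency and
   association profile in a second ancestry is incompatible with tagging the
   causal allele.
2. **Layered epigenetic prioritization.** The surviving tags are ranked by
   functional annotation: open-chromatin hotspots, 25-bp binned histone
   signal, promoter-capture interaction membership, and predicted
   allele-specific transcription-factor binding (ASTF) from position weight
   matrices. A *candidate* must sit in a chromatin interaction, in an
   open-chromatin hotspot, and show ASTF — a strict conjunction.

## Linkage disequilibrium and blocks

Two-locus LD is estimated from phased haplotypes by direct counting, or from
unphased diploid genotypes by EM over the double-heterozygote phase ambiguity
(`em_two_locus()`; convergence when the largest haplotype-frequency change
falls below 1e-9, cap 1000 iterations; missing genotypes handled
pairwise-complete, matching common LD tools). The EM preserves the observed
allele-frequency margins, so its single effective degree of freedom is the
coupling frequency; the test suite exploits this by checking the EM
likelihood against a 1-D grid search. Monomorphic pairs return a flagged
"undefined" result rather than NaN.

Blocks use the *solid spine of LD*: a run `[i..j]` is a block when both
boundary markers are in strong D' with every marker between them
(`D'(i,k) >= spine_dprime` and `D'(k,j) >= spine_dprime`). The default spine
threshold is 0.8, the convention of the tool that popularized the
definition; the confidence-interval block definition sometimes used
alongside it is deliberately not implemented. Detection is greedy
left-to-right to the largest admissible right boundary, which the tests show
equals exhaustive interval search. Ties at the threshold are accepted
(`>=`) for the spine, while the *inter-block* merge and the tag-SNP rule use
strict `>`, mirroring how the corresponding cut-offs are printed in the
applied literature (`> 0.75` in both cases). A flag relaxes the tag rule to
`>=` since both forms appear in print.

Adjacent blocks merge into a continuous risk region when their inter-block
D' exceeds `interblock_dprime = 0.75`. No standard definition exists for D'
between blocks, so the package defines it as the frequency-weighted average
of per-haplotype-pair |D'|, treating each block's haplotypes as alleles of a
multi-allelic locus; a simpler "major haplotype vs rest" variant is
available (`method = "major"`). Merging is transitive along the chain.

## Core intersection and exclusion mapping

`intersect_core()` drops populations whose risk-allele combination falls
below `min_freq = 0.001` (0.1% — a haplotype that rare carries no alignment
information), intersects the remaining merged-block intervals, and restricts
to tag-SNPs shared by every contributing population. Adding a population can
only narrow the core, and the result is invariant to population order; both
are property-tested.

Exclusion mapping classifies each discovery tag by its replication-ancestry
profile:

* **Group 2 (excluded)** — risk allele *commoner* in replication than in
  discovery, yet null there (`p > 0.01`), with replication OR below the null
  anchor, and a meta-analysis that fails to strengthen the discovery signal
  (pooled fixed-effect OR at or below the discovery OR, or `I^2 > 50`).
  These alleles are old: they ride many haplotype backgrounds in the
  replication ancestry and cannot tag the causal allele.
* **Group 1 (retained)** — risk allele very rare in replication
  (`MAF < 0.01`) while the replication association stays compatible with
  the discovery effect.

Two anchoring choices deserve comment. The null anchor `or_null` defaults to
the *index variant's* discovery lower confidence bound (the published
analysis used 1.14, which is exactly the index SNP's lower CI), not each
variant's own bound — anchoring a variant's null test to its own estimate
would be circular. And Group 1 compatibility defaults to a CI criterion
(replication upper CI reaches the discovery OR) rather than the literal
point comparison `OR_rep >= OR_disc`: at MAF below 1% a replication OR is
estimated from a few dozen alleles, its log has a standard error around 0.4,
and a point comparison against a precisely estimated discovery OR is a coin
flip for a genuinely causal tag. The CI form captures the intended
"still associated despite being rare" semantics and achieves the recovery
rates the point rule cannot; `group1_rule = "point"` restores the literal
rule. Variants meeting both definitions are flagged `unclassified` with a
warning rather than silently resolved, and every label carries a provenance
string naming the clauses that fired. "I > 50" in the source material is
read as `I^2 > 50` (the heterogeneity column of PLINK's meta-analysis is
I^2); `i2_cut` is configurable.

Group 1 subgrouping (`subgroup_1A_1B()`) needs a region map: 1A = inside the
regulatory interval with replication OR strictly above `or_strong = 1.5`;
1B = inside the coding interval; anything outside both stays plain Group 1
with a coverage-gap warning.

Meta-analysis is inverse-variance fixed effect plus DerSimonian–Laird
random effect on ln OR, with Cochran's Q and `I^2 = max(0, (Q - df)/Q) x
100` — the closed form PLINK reports, which for DL differs slightly from the
tau^2-based form some R packages print (the tests cross-check pooled
estimates against `metafor` and I^2 against the closed form). The allelic
association test is the 2x2 allele-count chi-square (Fisher's exact when an
expected cell drops below 5) with Woolf confidence intervals and the
Haldane–Anscombe 0.5 correction for zero cells; covariate-adjusted or
mixed-model association is out of scope. HWE uses the exact conditional
test (summation over heterozygote counts via the standard recurrence), with
a chi-square alternative behind a flag.

## Span arithmetic

Published haplotype coordinates are given as 1-based `chrN:a-b` strings, and
every printed kilobase figure at these loci reproduces under
`span = b - a`; the inclusive alternative `b - a + 1` does not, and is
rejected. One published figure is internally inconsistent: the refined
*IKZF1* core (chr7:50271064-50308811) computes to 37,747 bp, printed as
"47.7 kb" in the abstract and results but "37.7 kb" in the discussion. The
package reproduces the arithmetic (37.7 kb) and surfaces both printed
figures here rather than guessing intent.

## Annotation layers

Interval overlap is half-open and 0-based on the BED side: a variant at
1-based position `p` hits `[s, e)` iff `s <= p - 1 < e`. Internally tracks
are `GRanges` and all overlap goes through `IRanges`; the acceptance suite
checks the engine against a quadratic all-pairs oracle.

The histone layer is a 25-bp tiling. When a variant lies strictly closer
than 10 bp to the nearer edge of its bin, the value averages the containing
and adjacent bins; the distance is measured in bp from the variant base to
the nearer edge of the containing bin (the source rule does not define the
measure; this reading is configurable via `edge_bp`). A missing adjacent
bin falls back to the containing value.

DNase hotspot tiers sit at the two conventional SignalValue cut-offs, 2.5
and 5, strict `>` to match their printed form. Interaction membership is
per cell type, strict `>` on the fragment score (published thresholds 5.5
and 11 are passed as `min_score`). eQTL status is consumed as an input flag
per variant — the original analysis queried external databases, and no
attempt is made to recompute it. Genome-segmentation tracks use the seven
consensus ChromHMM/Segway labels as an enumerated vocabulary
(`segmentation_states`).

`prioritize()` is monotone by construction: raising any threshold can only
remove candidates, which is property-tested.

## Allele-specific TF binding

PWMs are column-stochastic with pseudocount 0.001 and uniform background,
scored in log2 odds — the convention of the HaploReg-style annotations this
module emulates (whether that pipeline's background is uniform or Markov is
not documented; uniform is chosen and stated). The 29-bp scan window places
the variant at the center, 14 bp each side; every motif placement
overlapping the variant base is scored on both strands and the best score
per allele kept. The LOD difference `alt - ref` is capped at +/-12,
mirroring the apparent saturation of published tables. Published LOD values
themselves are *not* reproduction targets: they depend on exact external
matrix libraries.

The stringency threshold is the smallest attainable score with background
tail probability at most `4^-8` — the probability of a single fixed 8-mer,
attainable only by near-consensus sequences of length >= 8. It is computed
by exact enumeration up to `4^L = 65536` and otherwise by exact dynamic
programming over per-column scores discretized to 0.01 log2 units; the two
routes agree exactly on the shared grid, and placement scores are compared
to the threshold with half-bin slack so discretization never flips a
genuine consensus hit. Stringency applies to the *better* allele (the
source rule is a disjunction over Ref and Alt). A hit additionally needs
`|delta| > 2` (strict), with a "strong" flag at `|delta| >= log2(3)`,
i.e. a predicted 3-fold binding change; both are configurable.

`shared_tf_pairs()` implements the bridging join: a distal hit and a
promoter hit pair when their motif names share the family token before the
first underscore (e.g. `RXRA_disc4` and `RXRA_known1`), with pairs flagged
when the promoter variant carries an eQTL annotation. This models the
potential for TF dimerization to stabilize chromatin loops; it makes no
biochemical claim.

## The simulator

`simulate_panel()` is a copying/recombination scheme, not a coalescent: a
haplotype is either a copy of the population's risk class — alternate
allele at every variant of its risk span, extending into the flank until a
geometric breakpoint (mean = `flank_extension`, hard-capped there) — or a
background haplotype with independent alternate alleles at logit-normal
drifted frequencies (base frequencies uniform on 0.1–0.5). Core alternate
alleles exist *only* on risk haplotypes, so core tags are in complete LD;
flank variants inside the extension share the risk background (high D')
but also segregate on background haplotypes, which dilutes r^2 below the
tagging threshold — the planted block may extend a variant or two into the
flank, the tag set does not. Two per-population knobs create the
trans-ancestral contrasts: `risk_span` widens the haplotype the risk class
carries (an extended population-specific haplotype whose extra tags are
ordinary background alleles elsewhere), and `bg_logit_shift` shifts
background frequencies directionally (old alleles common in one ancestry).
Phenotypes are assigned retrospectively under a logistic allelic model with
the intercept solved so the expected case fraction is met; at the odds
ratios used here the collapsibility error this introduces relative to
case/control ascertainment is well inside the stated test tolerances.

What the generator does *not* emulate: demographic realism (migration,
selection), genotyping or imputation error, X-linked inheritance, and
realistic annotation noise (tracks are planted cleanly over the functional
set). Passing recovery tests therefore demonstrate internal consistency of
the pipeline under its own assumptions, not performance on real cohorts.

Fixture generation plants one 8-bp motif per functional variant with the
variant at column 4, the alternate allele completing the consensus and the
reference allele disrupting it; information-rich columns (0.97 consensus
probability) make the `4^-8` stringency attainable. Adjacent functional
variants whose motif windows would overlap are rejected as ambiguous.

## Problem sizes and determinism

The test and acceptance suites run at desk scale, chosen to keep each
stochastic check's sampling error far from its pass boundary: 500
samples/population over 40 variants for block and tag recovery (10 seeds),
3000 samples/population at OR 2 for exclusion-group recovery (20 seeds,
>= 90% required per group), 1000 null variants at 400 samples for type-I
calibration (band 0.03–0.07 at alpha 0.05), and 8-variant panels for the
exhaustive block oracle. All randomness flows from a single run seed
through named per-stage substreams (`stage_seed()`), so identical
configurations are bit-identical end to end; the pipeline stamps every
output with a hash of the scientific configuration.

## Known limitations

* Inter-block D' requires phased haplotypes; unphased input is phased only
  pairwise (EM) or within blocks of at most 12 variants
  (`em_haplotypes()`, haplotype space 2^L).
* The allelic test assumes independent alleles (HWE in controls); the
  package does not implement genotypic or dosage-based association.
* Exclusion mapping presumes exactly one discovery and one replication
  ancestry; multi-way replication would need a pooling rule the source
  procedure does not define.
* Bayesian fine-mapping (posterior inclusion probabilities, credible sets)
  is intentionally absent — the method implemented here is the
  haplotype-alignment/exclusion procedure, not model-based inference.
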