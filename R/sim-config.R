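#' Population specification for the panel simulator
#'
#' @param name population label (e.g. "EUR", "AFR").
#' @param n_samples diploid sample count.
#' @param risk_hap_freq frequency of the planted risk haplotype class in
#'   this population, in `[0, 1]`.
#' @param flank_extension number of variants beyond the shared core that
#'   may still ride the risk haplotype in this population (the
#'   population-specific LD extension).
#' @param drift_sd standard deviation of the logit-normal perturbation
#'   applied to this population's background allele frequencies.
#' @param bg_logit_shift deterministic logit shift of the background
#'   frequencies, modelling directional frequency differentiation between
#'   ancestries (old alleles that are common in one population and rare in
#'   another). Default 0.
#' @param risk_span optional `c(a, b)` half-open variant-index interval of
#'   the alleles carried on this population's risk haplotype. Defaults to
#'   the shared `core_span`; a wider span models an extended
#'   population-specific risk haplotype whose extra tags are background
#'   alleles elsewhere.
#' @return a list with class `pop_spec`.
#' @export
pop_spec <- function(name, n_samples, risk_hap_freq,
                     flank_extension = 0L, drift_sd = 0,
                     bg_logit_shift = 0, risk_span = NULL) {
  if (risk_hap_freq < 0 || risk_hap_freq > 1) {
    stopf("risk_hap_freq must be in [0, 1]")
  }
  if (n_samples < 1) stopf("n_samples must be positive")
  if (drift_sd < 0) stopf("drift_sd must be non-negative")
  structure(
    list(name = name, n_samples = as.integer(n_samples),
         risk_hap_freq = risk_hap_freq,
         flank_extension = as.integer(flank_extension),
         drift_sd = drift_sd, bg_logit_shift = bg_logit_shift,
         risk_span = risk_span),
    class = "pop_spec"
  )
}

#' Simulation configuration
#'
#' Describes the planted truth for a multi-population panel: a shared
#' ancestral core risk haplotype (variant indices `[core_span[1],
#' core_span[2])`, half-open) whose alternate alleles exist only on the
#' risk haplotype class, one causal variant inside the core driving a
#' logistic case/control phenotype, and a designated functional subset of
#' variants used to plant annotation and motif fixtures.
#'
#' @param n_variants total variant count.
#' @param core_span half-open index interval `c(a, b)` of core variants
#'   (1-based indices, `b` exclusive).
#' @param index_variant index of the GWAS index variant, inside the core.
#' @param populations list of [pop_spec()] objects.
#' @param causal_variant index of the causal variant, inside the core.
#' @param causal_or allelic odds ratio of the causal variant (> 0).
#' @param case_fraction expected case fraction in `(0, 1)`.
#' @param functional_set variant indices designated functional.
#' @param chrom chromosome label used for emitted coordinates.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a list with class `sim_config`.
#' @export
sim_config <- function(n_variants, core_span, index_variant, populations,
                       causal_variant = index_variant, causal_or = 1,
                       case_fraction = 0.5, functional_set = integer(),
                       chrom = "chrS", seed = 1L) {
  n_variants <- as.integer(n_variants)
  core_span <- as.integer(core_span)
  if (length(core_span) != 2L || core_span[1] < 1L ||
      core_span[2] > n_variants + 1L || core_span[1] >= core_span[2]) {
    stopf("core_span must be a non-empty half-open interval within [1, n_variants]")
  }
  in_core <- function(i) i >= core_span[1] && i < core_span[2]
  if (!in_core(index_variant)) stopf("index_variant must lie inside core_span")
  if (!in_core(causal_variant)) stopf("causal_variant must lie inside core_span")
  if (causal_or <= 0) stopf("causal_or must be > 0")
  if (case_fraction <= 0 || case_fraction >= 1) {
    stopf("case_fraction must be in (0, 1)")
  }
  if (length(functional_set) &&
      (min(functional_set) < 1 || max(functional_set) > n_variants)) {
    stopf("functional_set indices out of range")
  }
  if (inherits(populations, "pop_spec")) populations <- list(populations)
  for (p in populations) {
    if (!inherits(p, "pop_spec")) stopf("populations must be pop_spec objects")
    if (!is.null(p$risk_span)) {
      rs <- as.integer(p$risk_span)
      if (rs[1] > core_span[1] || rs[2] < core_span[2]) {
        stopf("risk_span of population %s must contain core_span", p$name)
      }
      if (rs[1] < 1L || rs[2] > n_variants + 1L) stopf("risk_span out of range")
    }
  }
  structure(
    list(n_variants = n_variants, core_span = core_span,
         index_variant = as.integer(index_variant),
         populations = populations,
         causal_variant = as.integer(causal_variant),
         causal_or = causal_or, case_fraction = case_fraction,
         functional_set = as.integer(functional_set),
         chrom = chrom, seed = as.integer(seed)),
    class = "sim_config"
  )
}
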