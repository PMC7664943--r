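#' Simulate multi-population phased panels with a planted risk haplotype
#'
#' Uses a copying/recombination scheme rather than a coalescent: each
#' haplotype is either a copy of the population's risk haplotype class
#' (alternate allele at every variant of that population's risk span,
#' extending into the flank until a geometric recombination breakpoint)
#' or a background haplotype drawing independent alternate alleles at the
#' population's drifted background frequencies. Core-variant alternate
#' alleles exist only on risk haplotypes, so core tags are in complete LD
#' with each other; flank variants within the extension share the risk
#' background (high D') but also segregate on background haplotypes, so
#' their r2 with the index decays below the tagging threshold.
#'
#' @param config a [sim_config()].
#' @return named list of [phased_panel()] objects, one per population,
#'   with the simulation truth attached as attribute `"truth"`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  core <- config$core_span

  shared <- with_seed(stage_seed(config$seed, "variants"), {
    pos <- cumsum(sample(120:380, m, replace = TRUE)) + 100000L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(pos = as.integer(pos), ref = ref, alt = unname(alt),
         base_freq = runif(m, 0.1, 0.5))
  })
  variants <- data.frame(
    chrom = config$chrom, pos = shared$pos,
    id = sprintf("v%04d", seq_len(m)),
    ref = shared$ref, alt = shared$alt,
    stringsAsFactors = FALSE
  )

  core_idx <- seq.int(core[1], core[2] - 1L)
  panels <- list()
  for (pop in config$populations) {
    rs <- as.integer(pop$risk_span %||% core)
    risk_idx <- seq.int(rs[1], rs[2] - 1L)
    if (2 * pop$n_samples * pop$risk_hap_freq < 2) {
      stopf(paste0(
        "population %s is uninformative: expected risk-haplotype count ",
        "%.2f < 2 (raise n_samples or risk_hap_freq)"),
        pop$name, 2 * pop$n_samples * pop$risk_hap_freq)
    }
    panels[[pop$name]] <- with_seed(
      stage_seed(config$seed, paste0("panel:", pop$name)), {
        nh <- 2L * pop$n_samples
        bg <- inv_logit(logit(shared$base_freq) + pop$bg_logit_shift +
                          rnorm(m, 0, pop$drift_sd))
        bg[risk_idx] <- 0 # risk-span alt alleles are private to the risk class
        hap <- matrix(rbinom(nh * m, 1L, rep(bg, each = nh)), nrow = nh)
        is_risk <- rbinom(nh, 1L, pop$risk_hap_freq) == 1L
        if (any(is_risk)) {
          hap[is_risk, risk_idx] <- 1L
          f <- pop$flank_extension
          if (f > 0L) {
            pr <- 1 / (f + 1)
            for (h in which(is_risk)) {
              # geometric retention of the risk background into each flank,
              # hard-capped at the population's extension
              keep_l <- min(rgeom(1L, pr), f)
              keep_r <- min(rgeom(1L, pr), f)
              if (keep_l > 0L) {
                j <- rs[1] - seq_len(min(keep_l, rs[1] - 1L))
                hap[h, j] <- 1L
              }
              if (keep_r > 0L) {
                j <- rs[2] - 1L + seq_len(min(keep_r, m - rs[2] + 1L))
                hap[h, j] <- 1L
              }
            }
          }
        }
        phased_panel(variants, hap, rep(pop$name, pop$n_samples))
      })
  }
  attr(panels, "truth") <- list(
    config = config, base_freq = shared$base_freq,
    core_idx = core_idx,
    core_ids = variants$id[core_idx],
    index_id = variants$id[config$index_variant],
    causal_id = variants$id[config$causal_variant],
    functional_ids = variants$id[config$functional_set]
  )
  panels
}

#' @importFrom stats rnorm rgeom
NULL

#' Assign case/control phenotypes under a logistic allelic model
#'
#' Case probability is `plogis(a + log(causal_or) * dosage)` with the
#' intercept `a` solved numerically so the expected case fraction equals
#' `case_fraction` (retrospective assignment over the population sample,
#' not case/control ascertainment).
#'
#' @param panel a [phased_panel()].
#' @param causal_variant variant index or id.
#' @param causal_or allelic odds ratio (> 0).
#' @param case_fraction expected case fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return the panel with phenotypes filled in (1 = control, 2 = case).
#' @export
assign_phenotypes <- function(panel, causal_variant, causal_or,
                              case_fraction, seed) {
  if (causal_or <= 0) stopf("causal_or must be > 0")
  ci <- if (is.character(causal_variant)) variant_index(panel, causal_variant)
        else causal_variant
  d <- dosage_matrix(panel)[, ci]
  beta <- log(causal_or)
  a <- uniroot(function(a) mean(plogis(a + beta * d)) - case_fraction,
               c(-40, 40), tol = 1e-10)$root
  p <- plogis(a + beta * d)
  panel$phenotype <- with_seed(stage_seed(seed, "phenotype"),
                               ifelse(runif(length(p)) < p, 2L, 1L))
  panel
}
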