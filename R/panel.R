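#' Phased haplotype panel
#'
#' The central genotype container: an ordered variant table plus a
#' `2N x M` binary haplotype matrix (1 = alternate allele), two rows per
#' sample, with per-sample population and case/control labels. Phenotypes
#' use the PLINK convention: 1 = control, 2 = case, `NA` = missing.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based,
#'   strictly increasing within a chromosome), `id`, `ref`, `alt`.
#' @param haplotypes integer matrix, `2N x M`, entries 0/1 (`NA` allowed
#'   for missing calls; both rows of a sample are missing together).
#' @param population character vector, one label per sample.
#' @param phenotype integer vector per sample (1/2/`NA`).
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(variants, haplotypes, population,
                         phenotype = rep(NA_integer_, length(population))) {
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stopf("variants must have columns %s", paste(need, collapse = ", "))
  }
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) {
    stopf("haplotype matrix must have an even number of rows (2 per sample)")
  }
  n <- nrow(haplotypes) / 2L
  if (length(population) != n) {
    stopf("population labels (%d) must match sample count (%d)",
          length(population), n)
  }
  if (length(phenotype) != n) stopf("phenotype length must match sample count")
  if (ncol(haplotypes) != nrow(variants)) {
    stopf("haplotype columns (%d) must match variant count (%d)",
          ncol(haplotypes), nrow(variants))
  }
  bad <- !(haplotypes %in% c(0L, 1L, NA))
  if (any(bad)) stopf("haplotype entries must be 0, 1 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) stopf("positions must be strictly increasing on %s", ch)
  }
  colnames(haplotypes) <- variants$id
  structure(
    list(
      variants = variants,
      haplotypes = haplotypes,
      population = as.character(population),
      phenotype = as.integer(phenotype)
    ),
    class = "phased_panel"
  )
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf(
    "<phased_panel> %d samples (%s), %d variants, %s\n",
    n_samples(x),
    paste(unique(x$population), collapse = "/"),
    n_variants(x),
    if (all(is.na(x$phenotype))) "no phenotypes" else
      sprintf("%d cases / %d controls",
              sum(x$phenotype == 2L, na.rm = TRUE),
              sum(x$phenotype == 1L, na.rm = TRUE))
  ))
  invisible(x)
}

#' @rdname phased_panel
#' @param panel a `phased_panel`.
#' @export
n_samples <- function(panel) nrow(panel$haplotypes) %/% 2L

#' @rdname phased_panel
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Per-sample alternate-allele dosage matrix
#'
#' Collapses the two haplotype rows of each sample into 0/1/2 dosages
#' (`NA` where the call is missing).
#'
#' @param panel a `phased_panel`.
#' @return integer `N x M` matrix.
#' @export
dosage_matrix <- function(panel) {
  h <- panel$haplotypes
  idx <- seq_len(n_samples(panel))
  h[2L * idx - 1L, , drop = FALSE] + h[2L * idx, , drop = FALSE]
}

#' Subset a panel by variant and/or sample
#'
#' @param panel a `phased_panel`.
#' @param variants variant indices or ids to keep (default all).
#' @param samples sample indices to keep (default all).
#' @return a `phased_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(n_variants(panel))
        else if (is.character(variants)) match(variants, panel$variants$id)
        else variants
  if (anyNA(vi)) stopf("unknown variant id in subset")
  si <- samples %||% seq_len(n_samples(panel))
  hap_rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  phased_panel(panel$variants[vi, , drop = FALSE],
               panel$haplotypes[hap_rows, vi, drop = FALSE],
               panel$population[si], panel$phenotype[si])
}

variant_index <- function(panel, id) {
  i <- match(id, panel$variants$id)
  if (is.na(i)) stopf("variant '%s' not found in panel", id)
  i
}

# Allele frequency of the alternate allele per variant (haplotype-wise,
# missing-aware).
alt_freq <- function(panel) {
  colMeans(panel$haplotypes, na.rm = TRUE)
}
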