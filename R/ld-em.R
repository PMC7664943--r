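#' Two-locus haplotype frequencies and LD statistics
#'
#' For phased input the four two-locus haplotype frequencies are counted
#' directly; for unphased diploid genotypes they are estimated by EM over
#' the double-heterozygote phase ambiguity (convergence when the largest
#' haplotype-frequency change drops below `tol`, or after `max_iter`
#' iterations). Missing genotypes are handled pairwise-complete. Returns
#' D (haplotype-frequency covariance), D' (|D| over its maximum given the
#' allele frequencies) and r^2 (squared allelic correlation). If either
#' locus is monomorphic in the complete pairs the result is flagged
#' `defined = FALSE` and the LD measures are `NA` (never NaN arithmetic
#' downstream).
#'
#' @param panel a [phased_panel()].
#' @param i,j variant indices or ids.
#' @param phased use phase (`TRUE`), genotype EM (`FALSE`), or decide
#'   from the panel (`NA`, default: phased panels count directly).
#' @param tol,max_iter EM controls.
#' @return an `ld_stats` list: `D`, `D_prime`, `r2`, `hap_freqs` (pAB,
#'   pAb, paB, pab with A/B = alternate alleles), `em_iterations`,
#'   `converged`, `defined`, `n` (complete pairs).
#' @export
ld_pair <- function(panel, i, j, phased = NA, tol = 1e-9, max_iter = 1000L) {
  if (is.character(i)) i <- variant_index(panel, i)
  if (is.character(j)) j <- variant_index(panel, j)
  use_phase <- if (is.na(phased)) !anyNA(panel$haplotypes[, c(i, j)]) else phased

  if (use_phase) {
    hi <- panel$haplotypes[, i]
    hj <- panel$haplotypes[, j]
    ok <- !is.na(hi) & !is.na(hj)
    hi <- hi[ok]; hj <- hj[ok]
    n <- length(hi)
    if (n == 0L) return(ld_undefined(0L))
    f <- c(mean(hi & hj), mean(hi & !hj), mean(!hi & hj), mean(!hi & !hj))
    return(ld_from_freqs(f, n_iter = 0L, converged = TRUE, n = n))
  }

  g <- dosage_matrix(panel)
  gi <- g[, i]; gj <- g[, j]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (n == 0L) return(ld_undefined(0L))
  em <- em_two_locus(table(factor(gi, 0:2), factor(gj, 0:2)),
                     tol = tol, max_iter = max_iter)
  ld_from_freqs(em$hap_freqs, em$iterations, em$converged, n)
}

ld_undefined <- function(n) {
  structure(list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                 hap_freqs = rep(NA_real_, 4), em_iterations = 0L,
                 converged = TRUE, defined = FALSE, n = n),
            class = "ld_stats")
}

ld_from_freqs <- function(f, n_iter, converged, n) {
  names(f) <- c("AB", "Ab", "aB", "ab")
  pA <- f[["AB"]] + f[["Ab"]]
  pB <- f[["AB"]] + f[["aB"]]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    out <- ld_undefined(n)
    out$hap_freqs <- f
    return(out)
  }
  D <- f[["AB"]] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(
    D = D,
    D_prime = if (dmax > 0) min(1, abs(D) / dmax) else 0,
    r2 = min(1, D^2 / (pA * (1 - pA) * pB * (1 - pB))),
    hap_freqs = f, em_iterations = n_iter, converged = converged,
    defined = TRUE, n = n
  ), class = "ld_stats")
}

#' EM estimate of two-locus haplotype frequencies from a genotype table
#'
#' @param tab 3x3 genotype count table (rows: dosage 0/1/2 at locus 1;
#'   columns: dosage at locus 2).
#' @param tol convergence tolerance on the max haplotype-frequency change.
#' @param max_iter iteration cap.
#' @return list with `hap_freqs` (pAB, pAb, paB, pab), `iterations`,
#'   `converged`, `loglik`.
#' @export
em_two_locus <- function(tab, tol = 1e-9, max_iter = 1000L) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3L, 3L)))
  n <- sum(tab)
  # fixed haplotype contributions from unambiguous genotypes; the double
  # heterozygote tab[2,2] splits between AB/ab and Ab/aB couplings
  base <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  dh <- tab[2, 2]
  f <- rep(0.25, 4)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    counts <- base + dh * c(w, 1 - w, 1 - w, w)
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  list(hap_freqs = f, iterations = it, converged = converged,
       loglik = two_locus_loglik(tab, f))
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype
# frequencies (HWE at the haplotype level)
two_locus_loglik <- function(tab, f) {
  p <- matrix(0, 3, 3)
  # genotype probabilities from random union of haplotypes
  # dosage 0/1/2 at each locus; f = (AB, Ab, aB, ab)
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)) # alt indicators
  for (a in 1:4) for (b in 1:4) {
    d1 <- hap[a, 1] + hap[b, 1]
    d2 <- hap[a, 2] + hap[b, 2]
    p[d1 + 1, d2 + 1] <- p[d1 + 1, d2 + 1] + f[a] * f[b]
  }
  keep <- tab > 0
  sum(tab[keep] * log(p[keep]))
}
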