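#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are computed by the standard recurrence over adjacent
#' heterozygote counts. A chi-square alternative is available behind
#' `method = "chisq"`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major-hom, het, minor-hom; the
#'   labelling is symmetric).
#' @param method `"exact"` (default) or `"chisq"` (1 df, no continuity
#'   correction).
#' @return p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (method == "chisq") {
    p <- n_a / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
    return(pchisq(x2, df = 1, lower.tail = FALSE))
  }
  rare <- min(n_a, n_b)
  # feasible het counts share the parity of the rare-allele count
  het <- seq.int(rare %% 2L, rare, by = 2L)
  # unnormalized log-probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_hom_rare(h) * n_hom_common(h) / ((h+2)(h+1))
  logp <- numeric(length(het))
  for (i in seq_along(het)[-1]) {
    h <- het[i - 1L]
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    logp[i] <- logp[i - 1L] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_ab, het)
  if (is.na(obs)) stopf("inconsistent genotype counts for HWE test")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-9)]))
}

#' Variant quality-control filter
#'
#' Retains variants with minor allele frequency at or above `maf_min`,
#' Hardy-Weinberg exact-test p-value at or above `hwe_p_min` (computed in
#' controls when phenotypes are present), and genotype call rate strictly
#' above `call_rate_min`. Dropped variants are itemized with the first
#' failing rule.
#'
#' @param panel a [phased_panel()] (missing calls allowed).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE exact p (default 1e-4).
#' @param call_rate_min minimum fraction of typed individuals, strict
#'   (default 0.75).
#' @param hwe_method passed to [hwe_test()].
#' @return list with `panel` (filtered) and `report` (data.frame: id,
#'   maf, hwe_p, call_rate, pass, reason).
#' @export
qc_filter <- function(panel, maf_min = 0.01, hwe_p_min = 1e-4,
                      call_rate_min = 0.75, hwe_method = "exact") {
  g <- dosage_matrix(panel)
  call_rate <- colMeans(!is.na(g))
  p_alt <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_rows <- if (any(panel$phenotype == 2L, na.rm = TRUE)) {
    which(panel$phenotype == 1L)
  } else {
    seq_len(nrow(g))
  }
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[hwe_rows, j]
    gj <- gj[!is.na(gj)]
    hwe_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L),
             method = hwe_method)
  }, numeric(1))

  reason <- rep(NA_character_, ncol(g))
  reason[which(call_rate <= call_rate_min | is.na(maf) | is.nan(maf))] <- "call_rate"
  reason[which(is.na(reason) & maf < maf_min)] <- "maf"
  reason[which(is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_p_min)] <- "hwe"
  pass <- is.na(reason)
  report <- data.frame(
    id = panel$variants$id, maf = maf, hwe_p = hwe_p,
    call_rate = call_rate, pass = pass, reason = reason,
    stringsAsFactors = FALSE
  )
  if (!any(pass)) stopf("no variants survive QC")
  list(panel = subset_panel(panel, variants = which(pass)), report = report)
}
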