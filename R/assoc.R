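#' Allelic case/control association
#'
#' Per-variant 2x2 allelic test (alleles as observations): odds ratio of
#' the alternate (risk) allele in cases versus controls, Woolf 95%
#' confidence interval with the Haldane-Anscombe 0.5 correction when any
#' cell is zero, and a 1-df chi-square p-value (Fisher's exact test when
#' any expected cell count is below 5).
#'
#' @param panel a [phased_panel()] with phenotypes.
#' @param ancestry label recorded in the result (defaults to the panel's
#'   population label).
#' @return data.frame, one row per variant: `id`, `ancestry`, the allele
#'   counts (`risk_case`, `risk_ctrl`, `nonrisk_case`, `nonrisk_ctrl`),
#'   `or`, `ci_lo`, `ci_hi`, `p`, `maf_case`, `maf_ctrl`, `test`.
#' @export
allelic_association <- function(panel, ancestry = NULL) {
  if (all(is.na(panel$phenotype))) stopf("panel carries no phenotypes")
  ancestry <- ancestry %||% paste(unique(panel$population), collapse = "+")
  case <- rep(panel$phenotype == 2L, each = 2L)
  h <- panel$haplotypes
  out <- lapply(seq_len(ncol(h)), function(j) {
    hj <- h[, j]
    ok <- !is.na(hj) & !is.na(case)
    hj <- hj[ok]
    cs <- case[ok]
    a <- sum(hj == 1L & cs)       # risk allele in cases
    b <- sum(hj == 1L & !cs)      # risk allele in controls
    c_ <- sum(hj == 0L & cs)
    d <- sum(hj == 0L & !cs)
    st <- allelic_test(a, b, c_, d)
    data.frame(
      id = panel$variants$id[j], ancestry = ancestry,
      risk_case = a, risk_ctrl = b, nonrisk_case = c_, nonrisk_ctrl = d,
      or = st$or, ci_lo = st$ci_lo, ci_hi = st$ci_hi, p = st$p,
      maf_case = if (a + c_ > 0) a / (a + c_) else NA_real_,
      maf_ctrl = if (b + d > 0) b / (b + d) else NA_real_,
      test = st$test, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 2x2 allelic odds ratio, Woolf CI and test
#'
#' @param a,b,c_,d allele counts: risk/non-risk (rows) by case/control.
#' @return list `or`, `ci_lo`, `ci_hi`, `se_lnor`, `p`, `test`.
#' @export
allelic_test <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0)) stopf("allele counts must be nonnegative")
  corr <- if (any(counts == 0)) 0.5 else 0    # Haldane-Anscombe
  aa <- a + corr; bb <- b + corr; cc <- c_ + corr; dd <- d + corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- qnorm(0.975)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  p <- NA_real_
  test <- "chisq"
  if (n > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    expected <- outer(rowSums(tab), colSums(tab)) / n
    if (any(expected < 5)) {
      p <- fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
  } else {
    p <- 1
    test <- "degenerate"
  }
  list(or = or, ci_lo = exp(log(or) - z * se), ci_hi = exp(log(or) + z * se),
       se_lnor = se, p = p, test = test)
}

#' Fixed- and random-effects meta-analysis of per-ancestry odds ratios
#'
#' Inverse-variance weighting on the log odds ratio for the fixed
#' effect; DerSimonian-Laird for the random effect; Cochran's Q with
#' `k - 1` degrees of freedom; heterogeneity percentage
#' `I2 = max(0, (Q - df) / Q) * 100` (the form reported by PLINK's
#' meta-analysis, 0 when Q = 0).
#'
#' @param results data.frame with columns `id`, `ancestry`, `or`,
#'   and either `se_lnor` or the four allele-count columns emitted by
#'   [allelic_association()] (the SE is then recomputed with the same
#'   zero-cell correction).
#' @return data.frame per variant: `id`, `k`, `or_fixed`,
#'   `ci_lo_fixed`, `ci_hi_fixed`, `or_random`, `ci_lo_random`,
#'   `ci_hi_random`, `q`, `df`, `p_het`, `i2`, `tau2`.
#' @export
meta_analyze <- function(results) {
  if (!"se_lnor" %in% names(results)) {
    need <- c("risk_case", "risk_ctrl", "nonrisk_case", "nonrisk_ctrl")
    if (!all(need %in% names(results))) {
      stopf("results need se_lnor or the 2x2 allele counts")
    }
    cnt <- as.matrix(results[, need])
    corr <- ifelse(apply(cnt == 0, 1L, any), 0.5, 0)
    cnt <- cnt + corr
    results$se_lnor <- sqrt(rowSums(1 / cnt))
  }
  out <- lapply(split(results, results$id), function(df) {
    k <- nrow(df)
    if (k < 2L) {
      stopf("meta-analysis undefined for a single ancestry (variant %s)",
            df$id[1])
    }
    y <- log(df$or)
    v <- df$se_lnor^2
    if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0)) {
      stopf("non-finite ln OR or SE for variant %s", df$id[1])
    }
    w <- 1 / v
    yf <- sum(w * y) / sum(w)
    se_f <- sqrt(1 / sum(w))
    q <- sum(w * (y - yf)^2)
    dfq <- k - 1L
    i2 <- if (q > 0) max(0, (q - dfq) / q) * 100 else 0
    tau2 <- max(0, (q - dfq) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (v + tau2)
    yr <- sum(wr * y) / sum(wr)
    se_r <- sqrt(1 / sum(wr))
    z <- qnorm(0.975)
    data.frame(
      id = df$id[1], k = k,
      or_fixed = exp(yf), ci_lo_fixed = exp(yf - z * se_f),
      ci_hi_fixed = exp(yf + z * se_f),
      or_random = exp(yr), ci_lo_random = exp(yr - z * se_r),
      ci_hi_random = exp(yr + z * se_r),
      q = q, df = dfq, p_het = pchisq(q, dfq, lower.tail = FALSE),
      i2 = i2, tau2 = tau2, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- res[match(unique(results$id), res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
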