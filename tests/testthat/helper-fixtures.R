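# Shared fixture builders and independent oracles. Oracles are written
# against the definitions directly (enumeration / direct summation), not
# against the package's code paths.

# panel from an explicit haplotype matrix (one chromosome, evenly spaced)
panel_from_haps <- function(haps, pos = NULL, pop = "TST", ref = "A",
                            alt = "G") {
  m <- ncol(haps)
  pos <- pos %||% seq(1000L, by = 500L, length.out = m)
  variants <- data.frame(chrom = "chrT", pos = as.integer(pos),
                         id = sprintf("t%03d", seq_len(m)),
                         ref = rep_len(ref, m), alt = rep_len(alt, m),
                         stringsAsFactors = FALSE)
  phased_panel(variants, haps, rep(pop, nrow(haps) / 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# haplotype matrix realizing exact two-locus haplotype counts
haps_from_counts <- function(n_ab, n_aB, n_Ab, n_AB) {
  h <- rbind(
    matrix(rep(c(0L, 0L), n_ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), n_AB), ncol = 2, byrow = TRUE)
  )
  stopifnot(nrow(h) %% 2L == 0L)
  h
}

# direct-summation oracle for the HWE exact test (lgamma arithmetic,
# independent of the recurrence used by hwe_test)
hwe_exact_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (max(n_a, n_b) - h) / 2
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# 1-D grid-search oracle for the two-locus EM likelihood: the free
# parameter is f11 (the AB haplotype frequency); margins are fixed at the
# observed allele frequencies
two_locus_grid_oracle <- function(tab, n_grid = 200001L) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  pA <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * n)
  pB <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  f11 <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(f11, function(x) {
    f <- c(x, pA - x, pB - x, 1 - pA - pB + x)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 0)
    p <- matrix(0, 3, 3)
    hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    for (a in 1:4) for (b in 1:4) {
      d1 <- hap[a, 1] + hap[b, 1]
      d2 <- hap[a, 2] + hap[b, 2]
      p[d1 + 1, d2 + 1] <- p[d1 + 1, d2 + 1] + f[a] * f[b]
    }
    keep <- tab > 0
    if (any(p[keep] <= 0)) return(-Inf)
    sum(tab[keep] * log(p[keep]))
  }, numeric(1))
  list(f11 = f11[which.max(ll)], loglik = max(ll))
}

# exhaustive-interval oracle for solid-spine blocks: enumerate every
# contiguous interval satisfying the spine criterion, then take maximal
# non-overlapping intervals left to right
spine_oracle <- function(dp, tau) {
  m <- nrow(dp)
  ok <- function(i, j) {
    for (k in seq.int(i + 1L, j)) {
      if (is.na(dp[i, k]) || dp[i, k] < tau) return(FALSE)
    }
    for (k in seq.int(i, j - 1L)) {
      if (is.na(dp[k, j]) || dp[k, j] < tau) return(FALSE)
    }
    TRUE
  }
  valid <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (ok(i, j)) valid[[length(valid) + 1L]] <- c(i, j)
    }
  }
  picked <- list()
  at <- 1L
  while (length(valid)) {
    starts <- vapply(valid, `[`, integer(1), 1L)
    ends <- vapply(valid, `[`, integer(1), 2L)
    live <- starts >= at
    if (!any(live)) break
    i0 <- min(starts[live])
    j0 <- max(ends[live & starts == i0])
    picked[[length(picked) + 1L]] <- c(i0, j0)
    at <- j0 + 1L
  }
  picked
}

# quadratic all-pairs overlap oracle (1-based variant position vs
# 0-based half-open interval)
overlap_oracle <- function(pos, start0, end0) {
  hits <- list()
  for (i in seq_along(pos)) {
    for (j in seq_along(start0)) {
      if (start0[j] <= pos[i] - 1L && pos[i] - 1L < end0[j]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}

# exhaustive PWM score-threshold oracle over all 4^L sequences, using the
# same per-column binning as the DP so the two are exactly comparable
pwm_threshold_oracle <- function(p, p_value, bin = 0.01) {
  L <- p$length
  sc <- round(log2(p$matrix / rep(p$background, each = L)) / bin)
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- vapply(seq_len(nrow(seqs)), function(r) {
    sum(sc[cbind(seq_len(L), seqs[r, ])])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(seqs)), function(r) {
    prod(p$background[seqs[r, ]])
  }, numeric(1))
  s <- sort(unique(scores))
  tail <- vapply(s, function(x) sum(probs[scores >= x]), numeric(1))
  ok <- which(tail <= p_value * (1 + 1e-12))
  if (!length(ok)) return(list(threshold = Inf, attainable = FALSE))
  list(threshold = s[ok[1]] * bin, attainable = TRUE)
}

# standard two-population planted-core configuration used across tests
planted_config <- function(seed, n_samples = 500, n_variants = 40,
                           core = c(16, 26), index = 20,
                           flank = c(5, 2), risk = c(0.25, 0.18),
                           causal_or = 2, functional = integer()) {
  sim_config(
    n_variants = n_variants, core_span = core, index_variant = index,
    populations = list(
      pop_spec("EUR", n_samples, risk[1], flank_extension = flank[1]),
      pop_spec("AFR", n_samples, risk[2], flank_extension = flank[2])
    ),
    causal_variant = index, causal_or = causal_or, case_fraction = 0.5,
    functional_set = functional, seed = seed
  )
}
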