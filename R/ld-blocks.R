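#' Pairwise D' matrix
#'
#' Computes |D'| for every variant pair, from phase when available
#' (direct haplotype counting) or per-pair genotype EM otherwise.
#' Undefined pairs (a monomorphic locus) are `NA`.
#'
#' @param panel a [phased_panel()].
#' @param phased see [ld_pair()].
#' @return symmetric `M x M` matrix (diagonal `NA`).
#' @export
dprime_matrix <- function(panel, phased = NA) {
  h <- panel$haplotypes
  m <- ncol(h)
  use_phase <- if (is.na(phased)) !anyNA(h) else phased
  if (use_phase && !anyNA(h)) {
    n <- nrow(h)
    pab <- crossprod(h) / n
    p <- colMeans(h)
    D <- pab - outer(p, p)
    dmax_pos <- pmin(outer(p, 1 - p), outer(1 - p, p))
    dmax_neg <- pmin(outer(p, p), outer(1 - p, 1 - p))
    dmax <- ifelse(D >= 0, dmax_pos, dmax_neg)
    dp <- abs(D) / dmax
    dp[dmax == 0] <- 0
    poly <- p > 0 & p < 1
    dp[!poly, ] <- NA
    dp[, !poly] <- NA
    dp <- pmin(dp, 1)
  } else {
    dp <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        s <- ld_pair(panel, i, j, phased = phased)
        dp[i, j] <- dp[j, i] <- if (s$defined) s$D_prime else NA_real_
      }
    }
  }
  diag(dp) <- NA_real_
  dimnames(dp) <- list(panel$variants$id, panel$variants$id)
  dp
}

spine_valid <- function(dp, i, j, tau) {
  ks <- seq.int(i + 1L, j)
  left <- dp[i, ks]
  ks2 <- seq.int(i, j - 1L)
  right <- dp[ks2, j]
  all(!is.na(left) & left >= tau) && all(!is.na(right) & right >= tau)
}

#' Solid-spine haplotype blocks
#'
#' A block `[i..j]` requires both boundary markers to be in strong LD
#' with every marker of the block: `D'(i,k) >= spine_dprime` and
#' `D'(k,j) >= spine_dprime` for every `i < k <= j` resp. `i <= k < j`
#' (ties at the threshold are accepted). Blocks are found by greedy
#' left-to-right extension to the largest admissible right boundary, are
#' non-overlapping, ordered, and contain at least two markers.
#'
#' @param panel a QC-filtered [phased_panel()].
#' @param spine_dprime spine threshold (default 0.8).
#' @param dp optional precomputed [dprime_matrix()].
#' @return data.frame of blocks: `chrom`, `start_idx`, `end_idx`,
#'   `start_pos`, `end_pos`, `n_snps`, `population`, plus a `members`
#'   list-column of variant ids.
#' @export
solid_spine_blocks <- function(panel, spine_dprime = 0.8, dp = NULL) {
  dp <- dp %||% dprime_matrix(panel)
  m <- n_variants(panel)
  tau <- spine_dprime
  blocks <- list()
  i <- 1L
  while (i < m) {
    # left condition D'(i,k) >= tau is a prefix property in k; scan to its
    # first failure, then take the largest j whose right condition holds
    jmax <- i
    while (jmax < m && !is.na(dp[i, jmax + 1L]) && dp[i, jmax + 1L] >= tau) {
      jmax <- jmax + 1L
    }
    best <- NA_integer_
    if (jmax > i) {
      for (j in seq.int(jmax, i + 1L)) {
        if (spine_valid(dp, i, j, tau)) {
          best <- j
          break
        }
      }
    }
    if (!is.na(best)) {
      blocks[[length(blocks) + 1L]] <- c(i, best)
      i <- best + 1L
    } else {
      i <- i + 1L
    }
  }
  block_frame(panel, blocks)
}

block_frame <- function(panel, blocks) {
  v <- panel$variants
  pop <- unique(panel$population)
  if (!length(blocks)) {
    out <- data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      population = character(), stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  s <- vapply(blocks, `[`, integer(1), 1L)
  e <- vapply(blocks, `[`, integer(1), 2L)
  out <- data.frame(
    chrom = v$chrom[s], start_idx = s, end_idx = e,
    start_pos = v$pos[s], end_pos = v$pos[e],
    n_snps = e - s + 1L,
    population = paste(pop, collapse = "+"),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(seq_along(s), function(k) v$id[s[k]:e[k]])
  out
}

# block haplotype alleles: distinct patterns over member columns, with
# frequencies, from phased haplotypes
block_alleles <- function(panel, start_idx, end_idx) {
  h <- panel$haplotypes[, start_idx:end_idx, drop = FALSE]
  if (anyNA(h)) stopf("inter-block D' requires complete phased haplotypes")
  key <- apply(h, 1L, paste, collapse = "")
  tab <- table(key)
  list(key = key, freq = as.numeric(tab) / length(key),
       alleles = names(tab))
}

#' Multi-allelic D' between two haplotype blocks
#'
#' Treats each block's haplotypes as alleles of one multi-allelic locus
#' and returns the frequency-weighted average of the per-allele-pair
#' |D'| values (`method = "multiallelic"`, default), or the biallelic
#' |D'| of each block's major haplotype versus the rest
#' (`method = "major"`).
#'
#' @param panel a phased [phased_panel()].
#' @param b1,b2 rows of a [solid_spine_blocks()] frame (or any list with
#'   `start_idx`, `end_idx`).
#' @param method see above.
#' @return |D'| in `[0, 1]`.
#' @export
interblock_dprime <- function(panel, b1, b2,
                              method = c("multiallelic", "major")) {
  method <- match.arg(method)
  a1 <- block_alleles(panel, b1$start_idx, b1$end_idx)
  a2 <- block_alleles(panel, b2$start_idx, b2$end_idx)
  joint <- table(factor(a1$key, a1$alleles), factor(a2$key, a2$alleles))
  joint <- joint / sum(joint)
  p <- a1$freq
  q <- a2$freq
  pair_dp <- function(f_ab, pa, qb) {
    D <- f_ab - pa * qb
    dmax <- if (D >= 0) min(pa * (1 - qb), (1 - pa) * qb)
            else min(pa * qb, (1 - pa) * (1 - qb))
    if (dmax <= 0) 0 else min(1, abs(D) / dmax)
  }
  if (method == "major") {
    i <- which.max(p)
    j <- which.max(q)
    return(pair_dp(joint[i, j], p[i], q[j]))
  }
  tot <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(q)) {
      tot <- tot + p[i] * q[j] * pair_dp(joint[i, j], p[i], q[j])
    }
  }
  tot
}

#' Merge adjacent blocks into continuous risk regions
#'
#' Adjacent solid-spine blocks are merged when their multi-allelic
#' inter-block D' is strictly greater than `interblock_dprime`;
#' merging is transitive along the chain.
#'
#' @param blocks a [solid_spine_blocks()] frame.
#' @param panel the phased panel the blocks came from.
#' @param interblock_dprime merge threshold, strict (default 0.75).
#' @param method passed to [interblock_dprime()].
#' @return data.frame of merged regions: `chrom`, `start_idx`,
#'   `end_idx`, `start_pos`, `end_pos`, `n_blocks`, `block_rows`
#'   (list-column of merged block row indices), `members` (list-column
#'   of member ids across the merged blocks).
#' @export
merge_blocks <- function(blocks, panel, interblock_dprime = 0.75,
                         method = "multiallelic") {
  nb <- nrow(blocks)
  if (nb == 0L) return(blocks)
  link <- logical(max(nb - 1L, 0L))
  for (k in seq_len(nb - 1L)) {
    dp <- interblock_dprime(panel, blocks[k, ], blocks[k + 1L, ],
                            method = method)
    link[k] <- dp > interblock_dprime
  }
  grp <- cumsum(c(TRUE, !link))
  out <- do.call(rbind, lapply(split(seq_len(nb), grp), function(rows) {
    data.frame(
      chrom = blocks$chrom[rows[1]],
      start_idx = blocks$start_idx[rows[1]],
      end_idx = blocks$end_idx[rows[length(rows)]],
      start_pos = blocks$start_pos[rows[1]],
      end_pos = blocks$end_pos[rows[length(rows)]],
      n_blocks = length(rows),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$block_rows <- unname(split(seq_len(nb), grp))
  out$members <- lapply(out$block_rows, function(rows) {
    unlist(blocks$members[rows], use.names = FALSE)
  })
  out
}
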