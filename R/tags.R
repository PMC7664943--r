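#' Tag-SNP set around an index variant
#'
#' All variants whose r^2 with the index exceeds `r2_threshold`
#' (strict by default, mirroring the printed "r2 > 0.75" cut-off; set
#' `strict = FALSE` for ">="). The index itself is always a member
#' (r^2 = 1).
#'
#' @param panel a QC-filtered [phased_panel()].
#' @param index_variant variant id (or index).
#' @param r2_threshold tagging threshold (default 0.75).
#' @param strict use strict `>` (default) or `>=`.
#' @param qc_report optional [qc_filter()] report; if the index failed
#'   QC the error names the failing rule.
#' @return a `tag_set` list: `index`, `r2_threshold`, `members`
#'   (data.frame id, pos, r2), `span_bp` (max pos - min pos).
#' @export
tag_snps <- function(panel, index_variant, r2_threshold = 0.75,
                     strict = TRUE, qc_report = NULL) {
  if (!is.null(qc_report)) {
    row <- qc_report[qc_report$id == index_variant, ]
    if (nrow(row) == 1L && !row$pass) {
      stopf("index variant %s failed QC rule '%s'", index_variant, row$reason)
    }
  }
  ii <- if (is.character(index_variant)) variant_index(panel, index_variant)
        else index_variant
  p <- alt_freq(panel)[ii]
  if (is.na(p) || p <= 0 || p >= 1) {
    stopf("index variant %s is monomorphic", panel$variants$id[ii])
  }
  r2 <- vapply(seq_len(n_variants(panel)), function(j) {
    if (j == ii) return(1)
    s <- ld_pair(panel, ii, j)
    if (s$defined) s$r2 else NA_real_
  }, numeric(1))
  keep <- if (strict) which(!is.na(r2) & r2 > r2_threshold)
          else which(!is.na(r2) & r2 >= r2_threshold)
  keep <- union(ii, keep)
  members <- data.frame(
    id = panel$variants$id[keep],
    pos = panel$variants$pos[keep],
    r2 = r2[keep],
    stringsAsFactors = FALSE
  )
  members <- members[order(members$pos), ]
  rownames(members) <- NULL
  structure(list(
    index = panel$variants$id[ii],
    r2_threshold = r2_threshold,
    members = members,
    span_bp = max(members$pos) - min(members$pos)
  ), class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> index %s: %d members (r2 > %g), span %d bp\n",
              x$index, nrow(x$members), x$r2_threshold, x$span_bp))
  invisible(x)
}

#' Frequency of a risk-allele combination
#'
#' Frequency (and carrier count) of haplotypes carrying the stated risk
#' allele at every mapped variant. Phased panels are counted directly;
#' unphased genotypes are phased by within-block EM, refused above 12
#' variants (the haplotype space grows as 2^L).
#'
#' @param panel a [phased_panel()].
#' @param risk_alleles named character vector: variant id -> allele base.
#' @param phased force phased counting / EM; default decides from panel.
#' @return list: `frequency`, `carriers` (samples with >= 1 matching
#'   haplotype; expected count under the EM posterior for unphased
#'   input), `n_haplotypes`.
#' @export
risk_haplotype_frequency <- function(panel, risk_alleles, phased = NA) {
  ids <- names(risk_alleles)
  vi <- match(ids, panel$variants$id)
  if (anyNA(vi)) stopf("risk_alleles names missing from panel: %s",
                       paste(ids[is.na(vi)], collapse = ", "))
  v <- panel$variants[vi, ]
  # map each risk allele to 0 (ref) / 1 (alt); an allele matching neither
  # cannot be carried: frequency 0
  target <- integer(length(vi))
  for (k in seq_along(vi)) {
    a <- risk_alleles[[k]]
    target[k] <- if (a == v$alt[k]) 1L else if (a == v$ref[k]) 0L else NA_integer_
  }
  nh <- nrow(panel$haplotypes)
  if (anyNA(target)) {
    return(list(frequency = 0, carriers = 0L, n_haplotypes = nh))
  }
  use_phase <- if (is.na(phased)) !anyNA(panel$haplotypes[, vi]) else phased
  if (use_phase) {
    h <- panel$haplotypes[, vi, drop = FALSE]
    match_hap <- rowSums(h == rep(target, each = nh)) == length(target)
    ns <- n_samples(panel)
    carrier <- match_hap[2L * seq_len(ns) - 1L] | match_hap[2L * seq_len(ns)]
    return(list(frequency = mean(match_hap), carriers = sum(carrier),
                n_haplotypes = nh))
  }
  if (length(vi) > 12L) {
    stopf(paste0("EM phasing refused for %d variants: the haplotype space ",
                 "(2^L) is combinatorially intractable above 12"), length(vi))
  }
  em <- em_haplotypes(dosage_matrix(panel)[, vi, drop = FALSE])
  key <- paste(target, collapse = "")
  freq <- em$hap_freqs[key]
  if (is.na(freq)) freq <- 0
  list(frequency = unname(freq),
       carriers = round(sum(em$carrier_posterior[[key]] %||% 0), 2),
       n_haplotypes = nh)
}

#' Multi-locus haplotype-frequency EM for unphased genotypes
#'
#' @param g N x L dosage matrix (0/1/2, complete cases used).
#' @param tol,max_iter convergence controls.
#' @return list: `hap_freqs` named by 0/1 haplotype strings,
#'   `iterations`, `converged`, `carrier_posterior` (per haplotype, the
#'   per-sample posterior probability of carrying it).
#' @export
em_haplotypes <- function(g, tol = 1e-9, max_iter = 1000L) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  n <- nrow(g)
  L <- ncol(g)
  if (n == 0L) stopf("no complete genotypes for EM phasing")
  # expand each distinct genotype into its compatible (unordered)
  # haplotype pairs
  pat <- apply(g, 1L, paste, collapse = ",")
  tab <- table(pat)
  expand <- lapply(names(tab), function(p) {
    gg <- as.integer(strsplit(p, ",")[[1]])
    het <- which(gg == 1L)
    base <- ifelse(gg == 2L, 1L, 0L)
    if (!length(het)) {
      k <- paste(base, collapse = "")
      return(data.frame(h1 = k, h2 = k, stringsAsFactors = FALSE))
    }
    combos <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    h1 <- matrix(base, nrow(combos), L, byrow = TRUE)
    h2 <- h1
    h1[, het] <- combos
    h2[, het] <- 1L - combos
    k1 <- apply(h1, 1L, paste, collapse = "")
    k2 <- apply(h2, 1L, paste, collapse = "")
    key <- ifelse(k1 < k2, paste(k1, k2), paste(k2, k1))
    keep <- !duplicated(key)
    data.frame(h1 = k1[keep], h2 = k2[keep], stringsAsFactors = FALSE)
  })
  names(expand) <- names(tab)
  haps <- sort(unique(unlist(lapply(expand, function(d) c(d$h1, d$h2)))))
  f <- setNames(rep(1 / length(haps), length(haps)), haps)
  w <- as.numeric(tab)
  it <- 0L
  converged <- FALSE
  pair_post <- NULL
  while (it < max_iter) {
    it <- it + 1L
    counts <- setNames(numeric(length(haps)), haps)
    pair_post <- vector("list", length(expand))
    for (pi in seq_along(expand)) {
      d <- expand[[pi]]
      pr <- f[d$h1] * f[d$h2] * ifelse(d$h1 == d$h2, 1, 2)
      s <- sum(pr)
      post <- if (s > 0) pr / s else rep(1 / length(pr), length(pr))
      pair_post[[pi]] <- post
      for (r in seq_len(nrow(d))) {
        counts[d$h1[r]] <- counts[d$h1[r]] + w[pi] * post[r]
        counts[d$h2[r]] <- counts[d$h2[r]] + w[pi] * post[r]
      }
    }
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  # per-haplotype expected carrier count by genotype pattern
  carrier <- lapply(setNames(haps, haps), function(k) {
    vapply(seq_along(expand), function(pi) {
      d <- expand[[pi]]
      has <- d$h1 == k | d$h2 == k
      w[pi] * sum(pair_post[[pi]][has])
    }, numeric(1))
  })
  list(hap_freqs = f, iterations = it, converged = converged,
       carrier_posterior = carrier)
}
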