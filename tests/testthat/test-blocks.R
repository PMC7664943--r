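test_that("complete LD gives one block; equilibrium gives none", {
  # five perfectly coupled variants
  haps <- matrix(rep(rbinom(100, 1, 0.4), 5), ncol = 5)
  b <- solid_spine_blocks(panel_from_haps(haps))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_idx, b$end_idx), c(1L, 5L))

  # five independent variants at equilibrium: no multi-variant blocks
  set.seed(101)
  haps <- matrix(rbinom(100 * 5, 1, 0.5), ncol = 5)
  # force near-zero D' by construction: independent draws, then verify
  dp <- dprime_matrix(panel_from_haps(haps))
  b <- solid_spine_blocks(panel_from_haps(haps),
                          spine_dprime = max(dp, na.rm = TRUE) + 0.01)
  expect_equal(nrow(b), 0L)
})

test_that("greedy blocks equal the exhaustive-interval oracle on 8-variant panels", {
  for (s in 1:10) {
    set.seed(110 + s)
    n <- 120
    haps <- matrix(0L, 2 * n, 8)
    # two planted blocks with noisy copying plus independent columns
    bg <- rbinom(2 * n, 1, 0.5)
    for (j in 1:3) haps[, j] <- ifelse(runif(2 * n) < 0.9, bg, rbinom(2 * n, 1, 0.5))
    bg2 <- rbinom(2 * n, 1, 0.3)
    for (j in 5:7) haps[, j] <- ifelse(runif(2 * n) < 0.85, bg2, rbinom(2 * n, 1, 0.5))
    haps[, 4] <- rbinom(2 * n, 1, 0.4)
    haps[, 8] <- rbinom(2 * n, 1, 0.4)
    pan <- panel_from_haps(haps)
    dp <- dprime_matrix(pan)
    got <- solid_spine_blocks(pan, spine_dprime = 0.8, dp = dp)
    want <- spine_oracle(dp, 0.8)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_idx, vapply(want, `[`, integer(1), 1L))
      expect_equal(got$end_idx, vapply(want, `[`, integer(1), 2L))
    }
  }
})

test_that("block detection is invariant to sample order", {
  cfg <- planted_config(seed = 120, n_samples = 250)
  pan <- simulate_panel(cfg)$EUR
  b0 <- solid_spine_blocks(pan)
  set.seed(121)
  perm <- sample(n_samples(pan))
  pan2 <- subset_panel(pan, samples = perm)
  b1 <- solid_spine_blocks(pan2)
  expect_equal(b0$start_idx, b1$start_idx)
  expect_equal(b0$end_idx, b1$end_idx)
})

manual_blocks <- function(pan, bounds) {
  v <- pan$variants
  s <- vapply(bounds, `[`, integer(1), 1L)
  e <- vapply(bounds, `[`, integer(1), 2L)
  out <- data.frame(chrom = v$chrom[s], start_idx = s, end_idx = e,
                    start_pos = v$pos[s], end_pos = v$pos[e],
                    n_snps = e - s + 1L, population = "TST",
                    stringsAsFactors = FALSE)
  out$members <- lapply(seq_along(s), function(k) v$id[s[k]:e[k]])
  out
}

test_that("inter-block D' matches a direct frequency computation and drives merging", {
  # three 2-variant blocks with engineered haplotype couplings:
  # D'(block1, block2) = 0.9 and D'(block2, block3) = 0.5, built from
  # exact joint haplotype counts (x200 haplotypes)
  set.seed(130)
  n_hap <- 200L
  b2 <- rep(c(1L, 0L), each = 100L)
  b1 <- integer(n_hap)
  b1[b2 == 1L] <- rep(c(1L, 0L), c(95L, 5L))    # f(11) = 0.475
  b1[b2 == 0L] <- rep(c(1L, 0L), c(5L, 95L))
  b3 <- integer(n_hap)
  b3[b2 == 1L] <- rep(c(1L, 0L), c(75L, 25L))   # f(23) = 0.375
  b3[b2 == 0L] <- rep(c(1L, 0L), c(25L, 75L))
  haps <- cbind(b1, b1, b2, b2, b3, b3)
  ord <- sample(n_hap)                           # shuffle haplotype order
  pan <- panel_from_haps(haps[ord, ])
  blocks <- manual_blocks(pan, list(c(1L, 2L), c(3L, 4L), c(5L, 6L)))

  # direct frequency oracle (each block here has exactly 2 haplotype
  # alleles, so the weighted multi-allelic form reduces to biallelic D')
  direct_dp <- function(f11, pa, pb) {
    D <- f11 - pa * pb
    dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
            else min(pa * pb, (1 - pa) * (1 - pb))
    abs(D) / dmax
  }
  d12 <- interblock_dprime(pan, blocks[1, ], blocks[2, ])
  d23 <- interblock_dprime(pan, blocks[2, ], blocks[3, ])
  expect_equal(d12, direct_dp(0.475, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(d23, direct_dp(0.375, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(d12, 0.9, tolerance = 1e-12)
  expect_equal(d23, 0.5, tolerance = 1e-12)

  merged <- merge_blocks(blocks, pan, interblock_dprime = 0.75)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$start_idx, c(1L, 5L))     # first two merged only
  expect_equal(merged$end_idx, c(4L, 6L))

  # two blocks in complete coupling merge; independent blocks do not
  coupled <- panel_from_haps(cbind(b1, b1, b1, b1))
  mc <- merge_blocks(manual_blocks(coupled, list(c(1L, 2L), c(3L, 4L))),
                     coupled, interblock_dprime = 0.75)
  expect_equal(nrow(mc), 1L)

  shuffled <- sample(b3)                         # decouples block 2 from 1
  indep <- panel_from_haps(cbind(b1, b1, shuffled, shuffled))
  mi <- merge_blocks(manual_blocks(indep, list(c(1L, 2L), c(3L, 4L))),
                     indep, interblock_dprime = 0.75)
  expect_equal(nrow(mi), 2L)
})

test_that("tag sets recover the planted core exactly and honor thresholds", {
  ok <- 0L
  for (s in 1:5) {
    cfg <- planted_config(seed = 140 + s, n_samples = 500)
    pan <- simulate_panel(cfg)$EUR
    ts <- tag_snps(pan, "v0020")
    if (identical(sort(ts$members$id), sprintf("v%04d", 16:25))) ok <- ok + 1L
  }
  expect_equal(ok, 5L)

  # index alone above threshold -> singleton set, span 0
  set.seed(150)
  haps <- cbind(rbinom(400, 1, 0.4), rbinom(400, 1, 0.4), rbinom(400, 1, 0.4))
  pan <- panel_from_haps(haps)
  ts <- tag_snps(pan, "t002", r2_threshold = 0.75)
  expect_equal(ts$members$id, "t002")
  expect_equal(ts$span_bp, 0L)

  # degenerate threshold 0: all polymorphic variants with r2 > 0
  ts0 <- tag_snps(pan, "t002", r2_threshold = 0)
  r2s <- vapply(c(1, 3), function(j) ld_pair(pan, 2, j)$r2, numeric(1))
  expect_setequal(ts0$members$id, c("t002", c("t001", "t003")[r2s > 0]))

  # index that failed QC is refused with the rule named
  haps_rare <- cbind(haps, c(rep(1L, 3), rep(0L, 397)))
  pan2 <- panel_from_haps(haps_rare)
  qc <- qc_filter(pan2)
  expect_error(tag_snps(pan2, "t004", qc_report = qc$report), "maf")
})

test_that("risk-haplotype frequency tracks planted truth, degenerate maps, and EM phasing", {
  cfg <- planted_config(seed = 160, n_samples = 500, risk = c(0.25, 0.2))
  pan <- simulate_panel(cfg)$EUR
  v <- pan$variants
  core_ids <- sprintf("v%04d", 16:25)
  map <- setNames(v$alt[match(core_ids, v$id)], core_ids)
  rf <- risk_haplotype_frequency(pan, map)
  expect_lt(abs(rf$frequency - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))

  # single-variant map equals that allele's frequency
  one <- map[5]
  rf1 <- risk_haplotype_frequency(pan, one)
  expect_equal(rf1$frequency, mean(pan$haplotypes[, names(one)]))

  # allele absent from the panel
  bad <- setNames("N", core_ids[1])
  rf0 <- risk_haplotype_frequency(pan, bad)
  expect_equal(rf0$frequency, 0)
  expect_equal(rf0$carriers, 0L)

  # unphased EM within a small block approximates the phased count
  sub <- subset_panel(pan, variants = core_ids[1:4])
  rf_ph <- risk_haplotype_frequency(sub, map[1:4])
  rf_em <- risk_haplotype_frequency(sub, map[1:4], phased = FALSE)
  expect_lt(abs(rf_ph$frequency - rf_em$frequency), 0.02)

  # combinatorial refusal above 12 unphased variants
  cfg13 <- sim_config(16, c(2, 15), 8,
                      populations = pop_spec("EUR", 60, 0.3), seed = 161)
  pan13 <- simulate_panel(cfg13)$EUR
  ids13 <- pan13$variants$id[2:14]
  map13 <- setNames(pan13$variants$alt[2:14], ids13)
  expect_error(risk_haplotype_frequency(pan13, map13, phased = FALSE),
               "12")
})
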