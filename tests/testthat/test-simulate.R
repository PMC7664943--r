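test_that("identical configurations give bit-identical panels", {
  cfg <- planted_config(seed = 301, n_samples = 120)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$EUR$haplotypes, p2$EUR$haplotypes)
  expect_identical(p1$AFR$haplotypes, p2$AFR$haplotypes)
  expect_identical(p1$EUR$variants, p2$EUR$variants)
})

test_that("with zero drift both populations share expected allele frequencies", {
  cfg <- sim_config(
    30, c(11, 16), 12,
    populations = list(pop_spec("P1", 2500, 0.2, drift_sd = 0),
                       pop_spec("P2", 2500, 0.2, drift_sd = 0)),
    seed = 302
  )
  panels <- simulate_panel(cfg)
  f1 <- colMeans(panels$P1$haplotypes)
  f2 <- colMeans(panels$P2$haplotypes)
  # same generating frequencies: differences are pure binomial noise
  se <- sqrt(2 * pmax(f1, 0.01) * (1 - pmin(f1, 0.99)) / 5000)
  expect_true(all(abs(f1 - f2) < 5 * se))
})

test_that("planted core haplotype frequency matches the configured value", {
  cfg <- planted_config(seed = 303, n_samples = 500, risk = c(0.25, 0.25))
  panels <- simulate_panel(cfg)
  core_cols <- 16:25
  for (p in panels) {
    hits <- rowSums(p$haplotypes[, core_cols, drop = FALSE]) ==
      length(core_cols)
    freq <- mean(hits)
    se <- sqrt(0.25 * 0.75 / nrow(p$haplotypes))
    expect_lt(abs(freq - 0.25), 3 * se)
  }
})

test_that("an uninformative population (expected risk haplotypes < 2) is rejected", {
  cfg <- sim_config(
    20, c(8, 12), 9,
    populations = pop_spec("TINY", 50, 0.01),
    seed = 304
  )
  expect_error(simulate_panel(cfg), "uninformative")
})

test_that("a null causal odds ratio yields a null allelic association", {
  cfg <- sim_config(10, c(4, 7), 5,
                    populations = pop_spec("EUR", 4000, 0.3),
                    causal_or = 1, seed = 305)
  pan <- assign_phenotypes(simulate_panel(cfg)$EUR, 5, 1, 0.5, seed = 305)
  res <- allelic_association(pan)
  row <- res[res$id == "v0005", ]
  expect_true(row$ci_lo < 1 && 1 < row$ci_hi)
  expect_lt(abs(log(row$or)), 0.2)
})

test_that("the sampled allelic OR recovers the configured effect across replicates", {
  covered <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(5, c(2, 4), 3,
                      populations = pop_spec("EUR", 2000, 0.3),
                      causal_variant = 3, causal_or = 3, seed = 400 + s)
    pan <- assign_phenotypes(simulate_panel(cfg)$EUR, 3, 3, 0.5,
                             seed = 400 + s)
    row <- allelic_association(pan)
    row <- row[row$id == "v0003", ]
    if (row$ci_lo <= 3 && 3 <= row$ci_hi) covered <- covered + 1L
  }
  expect_gte(covered, 0.9 * n_rep)
})

test_that("the realized case fraction matches the configured fraction", {
  cfg <- sim_config(5, c(2, 4), 3,
                    populations = pop_spec("EUR", 5000, 0.3),
                    causal_or = 2, case_fraction = 0.5, seed = 306)
  pan <- assign_phenotypes(simulate_panel(cfg)$EUR, 3, 2, 0.5, seed = 306)
  frac <- mean(pan$phenotype == 2L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("track fixtures respect the planted functional structure", {
  cfg <- planted_config(seed = 307, n_samples = 100,
                        functional = c(17, 21))
  panels <- simulate_panel(cfg)
  fx <- generate_tracks(panels$EUR, c(17, 21), seed = 307)

  v <- panels$EUR$variants
  dn <- overlap_variants(v, fx$tracks$dnase)
  over_fun <- dn[dn$id %in% v$id[c(17, 21)], ]
  expect_true(all(over_fun$score > 5))
  over_bg <- dn[!dn$id %in% v$id[c(17, 21)], ]
  expect_true(all(over_bg$score < 2.5))

  # empty functional set: nothing above the lower hotspot tier anywhere
  fx0 <- generate_tracks(panels$EUR, integer(), seed = 307)
  dn0 <- overlap_variants(v, fx0$tracks$dnase)
  expect_true(all(dn0$score < 2.5))
  expect_length(fx0$pwms, 0)

  # 25-bp tiling: disjoint, contiguous, exactly 25 bp
  hb <- fx$tracks$histone
  starts <- GenomicRanges::start(hb) - 1L
  ends <- GenomicRanges::end(hb)
  expect_true(all(ends - starts == 25L))
  o <- order(starts)
  expect_true(all(starts[o][-1] == ends[o][-length(ends)]))
})

test_that("overlapping planted motifs for adjacent functional variants are rejected", {
  haps <- matrix(0L, 20, 4)
  pan <- panel_from_haps(haps, pos = c(1000L, 1010L, 1500L, 2000L))
  expect_error(generate_tracks(pan, c(1, 2), seed = 1), "overlap")
})
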