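vdf <- function(pos, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("q%03d", seq_along(pos)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

test_that("overlap boundary cases are exact", {
  tr <- annotation_track("dnase_hotspot", "chr1", start = 100, end = 125,
                         score = 7, name = "iv1")
  expect_equal(nrow(overlap_variants(vdf(100), tr)), 0L)
  expect_equal(nrow(overlap_variants(vdf(101), tr)), 1L)
  expect_equal(nrow(overlap_variants(vdf(125), tr)), 1L)
  expect_equal(nrow(overlap_variants(vdf(126), tr)), 0L)
  expect_equal(nrow(overlap_variants(vdf(110, chrom = "chr2"), tr)), 0L)
})

test_that("overlap engine matches the quadratic all-pairs oracle", {
  set.seed(240)
  n <- 300
  pos <- sample(1:5000, n)
  start0 <- sample(0:4950, n, replace = TRUE)
  end0 <- start0 + sample(1:80, n, replace = TRUE)
  tr <- annotation_track("genehancer_element", "chr1", start0, end0,
                         score = 1, name = sprintf("gh%03d", seq_len(n)))
  pos_sorted <- sort(pos)
  got <- overlap_variants(vdf(pos_sorted), tr)
  want <- overlap_oracle(pos_sorted, start0, end0)
  # compare as (variant position, interval) pair sets
  got_keys <- sort(paste(got$pos, got$interval_start, got$interval_end))
  want_keys <- sort(paste(pos_sorted[want[, 1]], start0[want[, 2]],
                          end0[want[, 2]]))
  expect_identical(got_keys, want_keys)
})

test_that("25-bp edge averaging follows the adjacency rule", {
  # three adjacent bins [0,25) [25,50) [50,75) with values 4, 8, 2
  tr <- annotation_track("histone_signal_25bp", "chr1",
                         start = c(0, 25, 50), end = c(25, 50, 75),
                         score = c(4, 8, 2), name = c("b1", "b2", "b3"),
                         cell_type = "GM")
  # center of bin 2 (0-based 37 -> >= 10 bp from both edges)
  expect_equal(signal_at_variant(list(chrom = "chr1", pos = 38), tr), 8)
  # 3 bp from the right edge of bin 1 (0-based 21): mean(4, 8) = 6
  expect_equal(signal_at_variant(list(chrom = "chr1", pos = 22), tr), 6)
  # 3 bp from the left edge of bin 1: no adjacent bin -> containing value
  expect_equal(signal_at_variant(list(chrom = "chr1", pos = 4), tr), 4)
  # result always within [min, max] of the bins consulted
  for (p in c(26, 30, 40, 48, 51, 60)) {
    v <- signal_at_variant(list(chrom = "chr1", pos = p), tr)
    expect_true(v >= 2 && v <= 8)
  }
  # outside the tiling
  expect_true(is.na(signal_at_variant(list(chrom = "chr1", pos = 90), tr)))
})

test_that("interaction membership uses a strict score threshold per cell type", {
  tr <- annotation_track(
    "interaction_fragment", "chr1",
    start = c(100, 100, 400), end = c(200, 200, 500),
    score = c(5.6, 5.5, 9), name = c("f1", "f1", "f2"),
    cell_type = c("tB", "nCD4", "tB")
  )
  v <- vdf(c(150, 450, 700))
  mem <- interaction_membership(v, tr, min_score = 5.5)
  m1 <- mem[mem$id == "q001", ]
  expect_true(m1$member[m1$cell_type == "tB"])         # 5.6 > 5.5
  expect_false(m1$member[m1$cell_type == "nCD4"])      # 5.5 not > 5.5
  m3 <- mem[mem$id == "q003", ]
  expect_true(all(!m3$member))                         # no fragment
})

test_that("prioritization is a strict conjunction and monotone in thresholds", {
  v <- vdf(c(150, 450, 800))
  tracks <- list(
    dnase = annotation_track("dnase_hotspot", "chr1",
                             start = c(100, 400, 760), end = c(200, 500, 840),
                             score = c(6, 6, 1.5),
                             name = c("d1", "d2", "d3")),
    interaction = annotation_track("interaction_fragment", "chr1",
                                   start = c(100, 760), end = c(200, 840),
                                   score = c(8, 8), name = c("f1", "f2"),
                                   cell_type = "tB")
  )
  astf <- data.frame(variant = c("q001", "q002", "q003"), delta = 2.5)
  pr <- prioritize(v, tracks, astf)
  expect_true(pr$candidate[pr$id == "q001"])    # all three layers
  expect_false(pr$candidate[pr$id == "q002"])   # no interaction
  expect_false(pr$candidate[pr$id == "q003"])   # hotspot below tier

  # dropping the ASTF layer removes the candidate
  pr_no_astf <- prioritize(v, tracks, astf[astf$variant != "q001", ])
  expect_false(any(pr_no_astf$candidate[pr_no_astf$id == "q001"]))

  # raising any threshold never adds a candidate
  base_set <- pr$id[pr$candidate]
  for (th in list(list(dnase_tiers = c(4, 7)),
                  list(interaction_min_score = 10))) {
    pr2 <- prioritize(v, tracks, astf, thresholds = th)
    expect_true(all(pr2$id[pr2$candidate] %in% base_set))
  }
  pr3 <- prioritize(v, tracks, astf,
                    thresholds = list(interaction_min_score = 7.9))
  expect_true(all(pr3$id[pr3$candidate] %in% base_set))
})
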