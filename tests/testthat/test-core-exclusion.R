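make_pop_entry <- function(chrom, start, end, ids, pos, freq) {
  list(block = list(chrom = chrom, start_pos = start, end_pos = end),
       tags = list(members = data.frame(id = ids, pos = pos,
                                        stringsAsFactors = FALSE)),
       risk_freq = freq)
}

test_that("core intersection: identity, narrowing, ordering, and frequency drops", {
  ids <- sprintf("s%02d", 1:6)
  pos <- c(100, 200, 300, 400, 500, 600)
  a <- make_pop_entry("chr1", 50, 650, ids, pos, 0.2)
  b <- make_pop_entry("chr1", 150, 550, ids[2:5], pos[2:5], 0.15)
  c_ <- make_pop_entry("chr1", 250, 650, ids[3:6], pos[3:6], 0.12)

  # single population: the core is its own merged block
  one <- intersect_core(list(A = a), "s03")
  expect_equal(c(one$start_pos, one$end_pos), c(50, 650))
  expect_equal(one$members, ids)

  # adding populations never widens the core (monotonicity)
  two <- intersect_core(list(A = a, B = b), "s03")
  three <- intersect_core(list(A = a, B = b, C = c_), "s03")
  expect_true(two$start_pos >= one$start_pos && two$end_pos <= one$end_pos)
  expect_true(three$start_pos >= two$start_pos &&
                three$end_pos <= two$end_pos)
  expect_true(all(three$members %in% two$members))
  expect_equal(three$members, c("s03", "s04", "s05"))

  # population-order invariance
  rev3 <- intersect_core(list(C = c_, B = b, A = a), "s03")
  expect_equal(rev3$start_pos, three$start_pos)
  expect_equal(rev3$end_pos, three$end_pos)
  expect_setequal(rev3$members, three$members)

  # a population carrying the risk haplotype below 0.1% is dropped
  rare <- make_pop_entry("chr1", 101, 149, ids[1], pos[1], 0.0005)
  with_rare <- intersect_core(list(A = a, B = b, R = rare), "s03")
  expect_equal(with_rare$dropped$population, "R")
  expect_match(with_rare$dropped$note, "excluded from intersection")
  expect_equal(with_rare$start_pos, two$start_pos)

  # empty interval intersection errors
  left <- make_pop_entry("chr1", 50, 150, ids[1:2], pos[1:2], 0.2)
  right <- make_pop_entry("chr1", 400, 650, ids[4:6], pos[4:6], 0.2)
  expect_error(intersect_core(list(L = left, R = right), "s01"),
               "no shared core")
})

test_that("span arithmetic reproduces printed interval lengths and guards", {
  s <- span_report("chr17", 37879762, 38074046, kb_precision = 0)
  expect_equal(s$span_bp, 194284)
  expect_equal(s$span_kb, 194)

  s <- span_report("chr17", 37920146, 38021117, kb_precision = 0,
                   reference = c(37879762, 38074046))
  expect_equal(s$span_bp, 100971)
  expect_equal(s$span_kb, 101)
  expect_gt(s$reduction_pct, 47)

  expect_error(span_report("chr1", 500, 500), "start < end")

  iv <- parse_interval("chr7:50,258,234-50,318,308")
  expect_equal(iv$chrom, "chr7")
  expect_equal(iv$end - iv$start, 60074)
})

fake_assoc <- function(id, or, ci_lo, ci_hi, p, maf_ctrl) {
  data.frame(id = id, ancestry = "X", or = or, ci_lo = ci_lo,
             ci_hi = ci_hi, p = p, maf_ctrl = maf_ctrl,
             stringsAsFactors = FALSE)
}

fake_meta <- function(id, or_fixed, i2) {
  data.frame(id = id, or_fixed = or_fixed, i2 = i2,
             stringsAsFactors = FALSE)
}

test_that("exclusion rules reproduce the canonical Group 1 / Group 2 profiles", {
  ids <- c("rsIndex", "rsG2", "rsG1")
  disc <- rbind(
    fake_assoc("rsIndex", 1.27, 1.14, 1.41, 1e-8, 0.036),
    fake_assoc("rsG2", 1.30, 1.10, 1.55, 1e-5, 0.03),
    fake_assoc("rsG1", 1.27, 1.12, 1.44, 1e-6, 0.036)
  )
  rep_ <- rbind(
    fake_assoc("rsIndex", 1.05, 0.9, 1.2, 0.3, 0.15),
    fake_assoc("rsG2", 1.05, 0.92, 1.19, 0.4, 0.15),   # common and null
    fake_assoc("rsG1", 1.6, 0.7, 3.6, 0.2, 0.0008)     # rare, associated
  )
  meta <- rbind(
    fake_meta("rsIndex", 1.15, 80),
    fake_meta("rsG2", 1.14, 80),
    fake_meta("rsG1", 1.3, 10)
  )
  res <- exclusion_mapping(ids[-1], disc, rep_, meta,
                           rules = list(index_variant = "rsIndex"))
  expect_equal(res$group[res$id == "rsG2"], "Group2")
  expect_equal(res$group[res$id == "rsG1"], "Group1")
  expect_true(all(nchar(res$provenance) > 0))

  # literal point rule also classifies the printed Group 1 profile
  res_pt <- exclusion_mapping(ids[-1], disc, rep_, meta,
                              rules = list(index_variant = "rsIndex",
                                           group1_rule = "point"))
  expect_equal(res_pt$group[res_pt$id == "rsG1"], "Group1")

  # idempotence: identical thresholds give identical labels
  res2 <- exclusion_mapping(ids[-1], disc, rep_, meta,
                            rules = list(index_variant = "rsIndex"))
  expect_identical(res$group, res2$group)

  # labels partition the inputs
  expect_setequal(res$id, ids[-1])
  expect_true(all(res$group %in% c("Group1", "Group2", "unclassified")))
})

test_that("a variant satisfying both group definitions is unclassified with a warning", {
  disc <- fake_assoc("rsX", 1.3, 1.1, 1.5, 1e-5, 0.03)
  # rare AND nominally "commoner": impossible in real data, constructed
  # by making maf_rep exceed maf_disc while below maf_rare
  disc$maf_ctrl <- 0.001
  rep_ <- fake_assoc("rsX", 1.0, 0.2, 5.0, 0.5, 0.005)
  meta <- fake_meta("rsX", 1.1, 70)
  expect_warning(
    res <- exclusion_mapping("rsX", disc, rep_, meta,
                             rules = list(or_null = 1.14)),
    "both group definitions")
  expect_equal(res$group, "unclassified")
})

test_that("Group 1 subgrouping follows region membership and replication OR", {
  region_map <- data.frame(
    chrom = "chr17",
    start = c(1000, 5000), end = c(3000, 9000),
    name = c("regulatory", "coding"), stringsAsFactors = FALSE
  )
  g1 <- data.frame(
    id = c("a", "b", "c", "d"),
    pos = c(2000, 6000, 2500, 12000),
    or_rep = c(1.6, 1.3, 1.3, 1.6),
    stringsAsFactors = FALSE
  )
  expect_warning(res <- subgroup_1A_1B(g1, region_map), "unsubgrouped")
  expect_equal(res$subgroup, c("Group1A", "Group1B", "Group1", "Group1"))
  expect_match(res$subgroup_provenance[1], "regulatory")
  expect_match(res$subgroup_provenance[2], "coding")
})
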