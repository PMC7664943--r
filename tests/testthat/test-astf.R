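# a deterministic fixture: 61-bp window, planted 8-mer motif with the
# variant completing (alt) or disrupting (ref) the consensus at column 4
astf_fixture <- function() {
  set.seed(260)
  bases <- c("A", "C", "G", "T")
  seq_chr <- sample(bases, 61, replace = TRUE)
  consensus <- strsplit("TGACGTCA", "")[[1]]
  # variant at genomic position 1031 = window index 31; motif occupies
  # indices 28..35 so the variant sits at motif column 4
  seq_chr[28:35] <- consensus
  seq_chr[31] <- "A"                       # ref disrupts column 4 ("C")
  rw <- ref_window("chrF", 1000L, Biostrings::DNAString(
    paste(seq_chr, collapse = "")))
  list(rw = rw,
       variant = list(id = "rsF", pos = 1031L, ref = "A", alt = "C"),
       pwm = consensus_pwm("FOXT_sim1", consensus))
}

test_that("the stringency threshold is exact for consensus, random, and flat motifs", {
  fx <- astf_fixture()
  th <- pwm_score_threshold(fx$pwm, p_value = 4^-8)
  expect_true(th$attainable)
  # only the consensus 8-mer passes: its probability is exactly 4^-8
  sc <- log2(fx$pwm$matrix / 0.25)
  consensus_score <- sum(apply(sc, 1L, max))
  # best non-consensus sequence loses the smallest per-column gap
  second_best <- consensus_score - min(apply(sc, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    s[1] - s[2]
  }))
  expect_lte(th$threshold, consensus_score + 0.05)  # 0.01-binned columns
  expect_gt(th$threshold, second_best)

  # DP equals exhaustive enumeration for short motifs
  set.seed(261)
  for (rep in 1:5) {
    m <- matrix(stats::rgamma(16, 1), 4, 4)
    m <- m / rowSums(m)
    p4 <- pwm(sprintf("RND%d_x", rep), m)
    for (pv in c(0.05, 0.01, 0.001)) {
      dp <- pwm_score_threshold(p4, p_value = pv, method = "dp")
      or_ <- pwm_threshold_oracle(p4, p_value = pv)
      expect_equal(dp$threshold, or_$threshold, tolerance = 1e-9)
    }
  }

  # a flat PWM scores 0 everywhere: 4^-8 unreachable below length 8
  flat <- pwm("FLAT_x", matrix(0.25, 6, 4))
  expect_false(pwm_score_threshold(flat, p_value = 4^-8)$attainable)

  expect_error(pwm_score_threshold(fx$pwm, p_value = 0), "p_value")
  expect_error(pwm_score_threshold(fx$pwm, p_value = 1), "p_value")
})

test_that("variant scanning detects the planted allele-specific site", {
  fx <- astf_fixture()
  r <- scan_variant(fx$pwm, fx$rw, fx$variant)
  expect_true(r$passes_stringency)
  expect_gt(r$delta, 2)
  expect_gt(r$best_alt, r$best_ref)
  expect_equal(r$alt_strand, "+")
  expect_lte(abs(r$delta), 12)
})

test_that("scan scores are invariant under reverse complementation", {
  fx <- astf_fixture()
  rc_seq <- Biostrings::reverseComplement(fx$rw$seq)
  # mirrored coordinates: window length 61, offset unchanged
  rc_rw <- ref_window("chrF", 1000L, rc_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_variant <- list(id = "rsF", pos = 1000L + (61L - 31L + 1L),
                     ref = unname(comp[fx$variant$ref]),
                     alt = unname(comp[fx$variant$alt]))
  r0 <- scan_variant(fx$pwm, fx$rw, fx$variant)
  r1 <- scan_variant(fx$pwm, rc_rw, rc_variant)
  expect_equal(r1$best_ref, r0$best_ref, tolerance = 1e-12)
  expect_equal(r1$best_alt, r0$best_alt, tolerance = 1e-12)
  expect_equal(r1$delta, r0$delta, tolerance = 1e-12)
})

test_that("scan rejects indels and truncated windows", {
  fx <- astf_fixture()
  indel <- list(id = "ins", pos = 1031L, ref = "A", alt = "AT")
  expect_error(scan_variant(fx$pwm, fx$rw, indel), "SNV")
  edge <- list(id = "edge", pos = 1005L, ref = "A", alt = "C")
  expect_error(scan_variant(fx$pwm, fx$rw, edge), "truncated")
})

test_that("allele-specific hit filtering is strict and family bridging joins work", {
  fx <- astf_fixture()
  v <- data.frame(chrom = "chrF", pos = 1031L, id = "rsF",
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  hits <- allele_specific_hits(v, list(fx$pwm), fx$rw)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$variant, "rsF")
  expect_true(hits$strong)                       # fold change >> 3

  # strict > on the delta cut-off: a cut equal to |delta| excludes the hit
  d <- abs(hits$delta)
  expect_equal(nrow(allele_specific_hits(v, list(fx$pwm), fx$rw,
                                         min_abs_delta = d)), 0L)
  expect_equal(nrow(allele_specific_hits(v, list(fx$pwm), fx$rw,
                                         min_abs_delta = d - 0.01)), 1L)

  # empty motif list
  expect_equal(nrow(allele_specific_hits(v, list(), fx$rw)), 0L)

  # shared-TF bridging by family token with eQTL flagging
  distal <- data.frame(variant = "rs11185603", motif = "RXRA_disc4",
                       family = "RXRA", stringsAsFactors = FALSE)
  promoter <- data.frame(variant = c("rs146295095", "rs999"),
                         motif = c("RXRA_known1", "STAT_disc2"),
                         family = c("RXRA", "STAT"),
                         stringsAsFactors = FALSE)
  eqtl <- data.frame(id = "rs146295095", eqtl = TRUE,
                     stringsAsFactors = FALSE)
  pairs <- shared_tf_pairs(distal, promoter, eqtl)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$family, "RXRA")
  expect_equal(pairs$promoter_variant, "rs146295095")
  expect_true(pairs$promoter_eqtl)

  none <- shared_tf_pairs(distal, promoter[promoter$family == "STAT", ])
  expect_equal(nrow(none), 0L)
})

test_that("strengthening a matched column never lowers the placement score", {
  fx <- astf_fixture()
  consensus <- strsplit("TGACGTCA", "")[[1]]
  base <- consensus_pwm("W_x", consensus, p_consensus = 0.7)
  strong <- consensus_pwm("S_x", consensus, p_consensus = 0.9)
  seq_score <- function(p, s) {
    sc <- log2(p$matrix / 0.25)
    sum(sc[cbind(seq_along(s), match(s, c("A", "C", "G", "T")))])
  }
  expect_gte(seq_score(strong, consensus), seq_score(base, consensus))
})
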