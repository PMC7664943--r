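#' Allele-specific PWM scan of a variant
#'
#' Builds the window of `window` bp centered on the variant (14 bp each
#' side for the default 29), substitutes each allele at the center, and
#' scores every motif placement overlapping the variant base on both
#' strands. Reports the best log2-odds score per allele, their
#' difference `delta = alt - ref` capped at +/- 12 (the saturation used
#' in published allele-specific binding tables), and whether the better
#' allele reaches the stringency threshold (default `p < 4^-8` under
#' the background).
#'
#' @param pwm a [pwm()].
#' @param refseq a [ref_window()] covering the variant +/- `(window-1)/2`.
#' @param variant list/one-row data.frame with `pos`, `id`, `ref`, `alt`
#'   (SNV only).
#' @param window odd window width (default 29).
#' @param stringency_p stringency tail probability (default `4^-8`).
#' @param threshold optional precomputed [pwm_score_threshold()] result.
#' @param delta_cap cap on `|delta|` (default 12).
#' @return an `lod_result` list: `variant`, `motif`, `family`,
#'   `best_ref`, `best_alt`, `delta`, `passes_stringency`,
#'   `ref_offset`, `ref_strand`, `alt_offset`, `alt_strand`.
#' @export
scan_variant <- function(pwm, refseq, variant, window = 29L,
                         stringency_p = 4^-8, threshold = NULL,
                         delta_cap = 12) {
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    stopf("scan_variant handles SNVs only (variant %s has ref '%s', alt '%s')",
          variant$id %||% "?", variant$ref, variant$alt)
  }
  if (window %% 2L != 1L) stopf("window must be odd")
  half <- (window - 1L) %/% 2L
  ci <- variant$pos - refseq$offset
  if (ci - half < 1L || ci + half > length(refseq$seq)) {
    stopf("window around %s (pos %d) is truncated by the sequence end",
          variant$id %||% "?", variant$pos)
  }
  win <- strsplit(as.character(
    Biostrings::subseq(refseq$seq, ci - half, ci + half)), "")[[1]]
  center <- half + 1L
  th <- threshold %||% pwm_score_threshold(pwm, p_value = stringency_p)
  sc <- pwm_score_table(pwm)
  L <- pwm$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best_for <- function(allele) {
    w <- win
    w[center] <- allele
    best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
    for (o in 0:(window - L)) {
      if (!(o + 1L <= center && center <= o + L)) next
      s <- w[(o + 1L):(o + L)]
      fwd <- sum(sc[cbind(seq_len(L), match(s, c("A", "C", "G", "T")))])
      rc <- rev(unname(comp[s]))
      rev_ <- sum(sc[cbind(seq_len(L), match(rc, c("A", "C", "G", "T")))])
      if (fwd > best$score) best <- list(score = fwd, offset = o, strand = "+")
      if (rev_ > best$score) best <- list(score = rev_, offset = o, strand = "-")
    }
    best
  }
  br <- best_for(variant$ref)
  ba <- best_for(variant$alt)
  delta <- max(-delta_cap, min(delta_cap, ba$score - br$score))
  # the threshold sits on a 0.01-per-column score grid; allow that
  # discretization when comparing exact placement scores against it
  slack <- 0.005 * L + 1e-9
  structure(list(
    variant = variant$id %||% NA_character_,
    motif = pwm$name, family = pwm$family,
    best_ref = br$score, best_alt = ba$score, delta = delta,
    passes_stringency = th$attainable &&
      max(br$score, ba$score) >= th$threshold - slack,
    ref_offset = br$offset, ref_strand = br$strand,
    alt_offset = ba$offset, alt_strand = ba$strand
  ), class = "lod_result")
}

#' Allele-specific TF binding hits across variants and motifs
#'
#' Scans every (variant, motif) pair and keeps those that reach the
#' stringency threshold for at least one allele AND whose absolute
#' ref/alt log-odds difference is strictly greater than
#' `min_abs_delta`. A `strong` flag marks predicted fold changes of at
#' least `strong_fold` (`|delta| >= log2(strong_fold)`).
#'
#' @param variants data.frame with `pos`, `id`, `ref`, `alt`.
#' @param pwms list of [pwm()] objects.
#' @param refseq a [ref_window()].
#' @param min_abs_delta LOD-difference cut-off, strict (default 2).
#' @param strong_fold fold-change marking strong hits (default 3).
#' @param stringency_p stringency tail probability (default `4^-8`).
#' @param window scan window (default 29).
#' @return data.frame: `variant`, `motif`, `family`, `ref_lod`,
#'   `alt_lod`, `delta`, `strand`, `offset`, `strong`.
#' @export
allele_specific_hits <- function(variants, pwms, refseq,
                                 min_abs_delta = 2, strong_fold = 3,
                                 stringency_p = 4^-8, window = 29L) {
  if (!length(pwms)) {
    return(data.frame(variant = character(), motif = character(),
                      family = character(), ref_lod = numeric(),
                      alt_lod = numeric(), delta = numeric(),
                      strand = character(), offset = integer(),
                      strong = logical(), stringsAsFactors = FALSE))
  }
  ths <- lapply(pwms, pwm_score_threshold, p_value = stringency_p)
  rows <- list()
  for (k in seq_along(pwms)) {
    for (i in seq_len(nrow(variants))) {
      r <- scan_variant(pwms[[k]], refseq, variants[i, ], window = window,
                        stringency_p = stringency_p, threshold = ths[[k]])
      if (r$passes_stringency && abs(r$delta) > min_abs_delta) {
        alt_best <- r$best_alt >= r$best_ref
        rows[[length(rows) + 1L]] <- data.frame(
          variant = r$variant, motif = r$motif, family = r$family,
          ref_lod = r$best_ref, alt_lod = r$best_alt, delta = r$delta,
          strand = if (alt_best) r$alt_strand else r$ref_strand,
          offset = if (alt_best) r$alt_offset else r$ref_offset,
          strong = abs(r$delta) >= log2(strong_fold),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(allele_specific_hits(variants, list(), refseq))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared-TF bridging pairs between distal and promoter variants
#'
#' Pairs every distal allele-specific hit with every promoter hit whose
#' motif belongs to the same TF family (the name token before the first
#' underscore), modelling the potential for TF dimerization to bridge a
#' chromatin loop. Pairs are flagged when the promoter variant carries
#' an eQTL annotation.
#'
#' @param distal_hits,promoter_hits [allele_specific_hits()] frames.
#' @param eqtl_flags optional data.frame `id`, `eqtl` (logical).
#' @return data.frame: `distal_variant`, `promoter_variant`, `family`,
#'   `distal_motif`, `promoter_motif`, `promoter_eqtl`.
#' @export
shared_tf_pairs <- function(distal_hits, promoter_hits, eqtl_flags = NULL) {
  out <- merge(
    data.frame(distal_variant = distal_hits$variant,
               family = distal_hits$family,
               distal_motif = distal_hits$motif, stringsAsFactors = FALSE),
    data.frame(promoter_variant = promoter_hits$variant,
               family = promoter_hits$family,
               promoter_motif = promoter_hits$motif, stringsAsFactors = FALSE),
    by = "family"
  )
  out <- unique(out)
  out$promoter_eqtl <- logical(nrow(out))
  if (!is.null(eqtl_flags) && nrow(out)) {
    flagged <- eqtl_flags$id[eqtl_flags$eqtl]
    out$promoter_eqtl <- out$promoter_variant %in% flagged
  }
  rownames(out) <- NULL
  out[, c("distal_variant", "promoter_variant", "family",
          "distal_motif", "promoter_motif", "promoter_eqtl")]
}
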