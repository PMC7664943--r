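#' Genome-segmentation state vocabulary
#'
#' The seven consensus ChromHMM/Segway segmentation labels used for
#' `segmentation_state` tracks.
#' @export
segmentation_states <- c(
  "Predicted promoter including TSS",
  "Predicted promoter flanking region",
  "Predicted enhancer",
  "Predicted weak enhancer or open chromatin cis regulatory element",
  "CTCF enriched element",
  "Predicted transcribed region",
  "Predicted Repressed or Low Activity region"
)

#' Overlap variants with a scored annotation track
#'
#' A variant at 1-based position `p` hits a 0-based half-open interval
#' `[s, e)` iff `s <= p - 1 < e` (i.e. 1-based containment). Overlap is
#' computed with `IRanges`; a chromosome mismatch simply yields no hits.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `id`.
#' @param track an [annotation_track()].
#' @return data.frame of hits: `id`, `pos`, `interval_start` (0-based),
#'   `interval_end`, `score`, `name`, `cell_type`.
#' @export
overlap_variants <- function(variants, track) {
  vgr <- variants_gr(variants)
  # a chromosome mismatch is a legitimate zero-hit case, not a condition
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(vgr, track, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  data.frame(
    id = variants$id[q],
    pos = variants$pos[q],
    interval_start = GenomicRanges::start(track)[s] - 1L,
    interval_end = GenomicRanges::end(track)[s],
    score = track$score[s],
    name = track$name[s],
    cell_type = track$cell_type[s],
    stringsAsFactors = FALSE
  )
}

#' Histone signal at a variant with 25-bp edge averaging
#'
#' Returns the value of the 25-bp bin containing the variant; when the
#' variant base lies strictly closer than `edge_bp` to the nearer edge
#' of its bin, the mean of the containing bin and the adjacent bin on
#' that side is returned instead (containing bin only when no adjacent
#' bin exists). Distance is measured in bp from the variant base to the
#' nearer bin edge, strict `<`.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`.
#' @param track a `histone_signal_25bp` [annotation_track()].
#' @param cell_type restrict to one cell type (default: the track's
#'   first).
#' @param edge_bp edge-averaging distance (default 10).
#' @return numeric value (`NA` when no bin contains the variant).
#' @export
signal_at_variant <- function(variant, track, cell_type = NULL,
                              edge_bp = 10L) {
  if (track_class(track) != "histone_signal_25bp") {
    stopf("signal_at_variant expects a histone_signal_25bp track")
  }
  cell_type <- cell_type %||% track$cell_type[1]
  tr <- track[track$cell_type %in% cell_type]
  p0 <- variant$pos - 1L   # 0-based base coordinate
  s0 <- GenomicRanges::start(tr) - 1L
  e0 <- GenomicRanges::end(tr)
  ix <- which(as.character(GenomicRanges::seqnames(tr)) == variant$chrom &
                s0 <= p0 & p0 < e0)
  if (!length(ix)) return(NA_real_)
  ix <- ix[1]
  val <- tr$score[ix]
  dist_left <- p0 - s0[ix]
  dist_right <- (e0[ix] - 1L) - p0
  if (min(dist_left, dist_right) >= edge_bp) return(val)
  # adjacent bin on the nearer side, if the tiling continues there
  want_start <- if (dist_left < dist_right) s0[ix] - 25L else e0[ix]
  adj <- which(s0 == want_start &
                 as.character(GenomicRanges::seqnames(tr)) == variant$chrom)
  if (!length(adj)) return(val)
  mean(c(val, tr$score[adj[1]]))
}

#' Chromatin-interaction membership per cell type
#'
#' A variant is a member of the interaction landscape of a cell type
#' iff it overlaps a fragment whose score in that cell type is strictly
#' greater than `min_score`. The maximum overlapping score per cell
#' type is retained.
#'
#' @param variants data.frame with `chrom`, `pos`, `id`.
#' @param track an `interaction_fragment` [annotation_track()] with one
#'   row per (fragment, cell type).
#' @param min_score membership threshold, strict (default 5).
#' @return data.frame: `id`, `cell_type`, `member`, `max_score`.
#' @export
interaction_membership <- function(variants, track, min_score = 5) {
  if (track_class(track) != "interaction_fragment") {
    stopf("interaction_membership expects an interaction_fragment track")
  }
  cell_types <- unique(track$cell_type)
  hits <- overlap_variants(variants, track)
  out <- expand.grid(id = variants$id, cell_type = cell_types,
                     stringsAsFactors = FALSE)
  out$max_score <- NA_real_
  out$member <- FALSE
  if (nrow(hits)) {
    key <- paste(hits$id, hits$cell_type)
    mx <- tapply(hits$score, key, max)
    okey <- paste(out$id, out$cell_type)
    out$max_score <- as.numeric(mx[okey])
    out$member <- !is.na(out$max_score) & out$max_score > min_score
  }
  out
}

#' Layered functional prioritization of tag-SNPs
#'
#' Combines the annotation layers into a per-variant report and flags
#' candidates: a variant is a candidate iff it is a member of a
#' chromatin interaction in at least one cell type, sits in an
#' open-chromatin hotspot above the lower tier, and shows predicted
#' allele-specific TF binding. DNase tiers follow the two conventional
#' SignalValue cut-offs (strictly above 2.5; strictly above 5).
#'
#' @param variants data.frame with `chrom`, `pos`, `id`.
#' @param tracks named list of [annotation_track()]s; recognized names:
#'   `dnase`, `histone`, `interaction`, `genehancer`, `segmentation`.
#' @param astf_hits [allele_specific_hits()] result (or any data.frame
#'   with a `variant` column of ids with predicted ASTF).
#' @param thresholds list: `dnase_tiers` (c(2.5, 5)),
#'   `interaction_min_score` (5), `eqtl_flags` optional data.frame
#'   (`id`, `eqtl`).
#' @return a `priority_report` data.frame sorted by (candidate, tier,
#'   interaction score): `id`, `pos`, `in_interaction`,
#'   `interaction_max`, `dnase_tier` ("none"/"gt2.5"/"gt5"),
#'   `dnase_max`, `histone_value`, `segmentation_state`,
#'   `genehancer_ids`, `eqtl`, `has_astf`, `candidate`.
#' @export
prioritize <- function(variants, tracks, astf_hits, thresholds = list()) {
  th <- modifyList(list(dnase_tiers = c(2.5, 5), interaction_min_score = 5,
                        eqtl_flags = NULL), thresholds)
  n <- nrow(variants)
  res <- data.frame(id = variants$id, pos = variants$pos,
                    stringsAsFactors = FALSE)

  res$in_interaction <- FALSE
  res$interaction_max <- NA_real_
  if (!is.null(tracks$interaction)) {
    mem <- interaction_membership(variants, tracks$interaction,
                                  min_score = th$interaction_min_score)
    agg_mem <- tapply(mem$member, mem$id, any)
    agg_max <- suppressWarnings(tapply(mem$max_score, mem$id,
                                       function(x) if (all(is.na(x))) NA_real_
                                                   else max(x, na.rm = TRUE)))
    res$in_interaction <- as.logical(agg_mem[res$id])
    res$interaction_max <- as.numeric(agg_max[res$id])
  }

  res$dnase_max <- NA_real_
  res$dnase_tier <- "none"
  if (!is.null(tracks$dnase)) {
    hits <- overlap_variants(variants, tracks$dnase)
    if (nrow(hits)) {
      mx <- tapply(hits$score, hits$id, max)
      res$dnase_max <- as.numeric(mx[res$id])
    }
    res$dnase_tier <- ifelse(
      !is.na(res$dnase_max) & res$dnase_max > th$dnase_tiers[2], "gt5",
      ifelse(!is.na(res$dnase_max) & res$dnase_max > th$dnase_tiers[1],
             "gt2.5", "none"))
  }

  res$histone_value <- NA_real_
  if (!is.null(tracks$histone)) {
    res$histone_value <- vapply(seq_len(n), function(i) {
      signal_at_variant(variants[i, ], tracks$histone)
    }, numeric(1))
  }

  res$segmentation_state <- NA_character_
  if (!is.null(tracks$segmentation)) {
    hits <- overlap_variants(variants, tracks$segmentation)
    if (nrow(hits)) {
      st <- tapply(hits$name, hits$id, function(x) paste(unique(x), collapse = ";"))
      res$segmentation_state <- as.character(st[res$id])
    }
  }

  res$genehancer_ids <- NA_character_
  if (!is.null(tracks$genehancer)) {
    hits <- overlap_variants(variants, tracks$genehancer)
    if (nrow(hits)) {
      gh <- tapply(hits$name, hits$id, function(x) paste(unique(x), collapse = ";"))
      res$genehancer_ids <- as.character(gh[res$id])
    }
  }

  res$eqtl <- FALSE
  if (!is.null(th$eqtl_flags)) {
    res$eqtl <- res$id %in% th$eqtl_flags$id[th$eqtl_flags$eqtl]
  }

  astf_ids <- unique(astf_hits$variant %||% character())
  res$has_astf <- res$id %in% astf_ids
  res$candidate <- res$in_interaction & res$dnase_tier != "none" & res$has_astf

  tier_rank <- match(res$dnase_tier, c("none", "gt2.5", "gt5"))
  ord <- order(-res$candidate, -tier_rank,
               -ifelse(is.na(res$interaction_max), -Inf, res$interaction_max))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("priority_report", class(res))
  res
}
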