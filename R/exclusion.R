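#' Trans-ancestral exclusion mapping
#'
#' Partitions the tag-SNPs of a core risk haplotype by the consistency
#' of their frequency/association profile across a discovery and a
#' replication ancestry.
#'
#' A variant is excluded (**Group 2**: its risk allele rides other,
#' older haplotype backgrounds in the replication ancestry and cannot
#' tag the causal allele) when its replication risk-allele frequency
#' exceeds the discovery frequency AND the replication association is
#' null (`p > p_thresh`) AND the replication OR sits below the null
#' anchor `or_null` AND the meta-analysis does not strengthen the
#' discovery signal (pooled fixed-effect OR at or below the discovery
#' OR, or heterogeneity `I2 > i2_cut`).
#'
#' A variant is retained (**Group 1**: compatible with tagging the
#' causal allele) when its risk allele is very rare in the replication
#' ancestry (`MAF < maf_rare`) while the replication association
#' remains compatible with the discovery effect. With the default
#' `group1_rule = "ci"` compatibility means the replication 95% CI
#' reaches the discovery OR (a point comparison against a rare-allele
#' OR is dominated by sampling noise); `group1_rule = "point"` applies
#' the literal `OR_rep >= OR_disc`.
#'
#' Variants satisfying both definitions are flagged `unclassified` with
#' a warning (never silently overridden); variants satisfying neither
#' are `unclassified`.
#'
#' @param tags character vector of tag-SNP ids to classify.
#' @param assoc_disc,assoc_rep [allelic_association()] frames for the
#'   discovery and replication ancestries.
#' @param meta [meta_analyze()] frame over both.
#' @param rules list overriding defaults: `p_thresh` (0.01), `maf_rare`
#'   (0.01), `i2_cut` (50), `or_null` (`NULL` = the discovery lower-CI
#'   bound of `index_variant`), `index_variant`, `group1_rule`
#'   ("ci"/"point").
#' @return data.frame: `id`, `group` (`Group1`/`Group2`/`unclassified`),
#'   `provenance` (the clauses that fired), plus the inputs used.
#' @export
exclusion_mapping <- function(tags, assoc_disc, assoc_rep, meta,
                              rules = list()) {
  r <- modifyList(list(p_thresh = 0.01, maf_rare = 0.01, i2_cut = 50,
                       or_null = NULL, index_variant = NULL,
                       group1_rule = "ci"), rules)
  if (is.null(r$or_null)) {
    if (is.null(r$index_variant)) {
      stopf("rules must supply or_null or index_variant (its discovery lower CI anchors the null bound)")
    }
    row <- assoc_disc[assoc_disc$id == r$index_variant, ]
    if (nrow(row) != 1L) stopf("index variant %s absent from discovery results",
                               r$index_variant)
    r$or_null <- row$ci_lo
  }
  d <- assoc_disc[match(tags, assoc_disc$id), ]
  p <- assoc_rep[match(tags, assoc_rep$id), ]
  mm <- meta[match(tags, meta$id), ]
  if (anyNA(d$id) || anyNA(p$id) || anyNA(mm$id)) {
    stopf("tags must be present in discovery, replication and meta results")
  }
  out <- lapply(seq_along(tags), function(i) {
    maf_d <- d$maf_ctrl[i]
    maf_r <- p$maf_ctrl[i]
    clauses2 <- c(
      maf = maf_r > maf_d,
      null_p = p$p[i] > r$p_thresh,
      null_or = p$or[i] < r$or_null,
      meta = (mm$or_fixed[i] <= d$or[i]) || (mm$i2[i] > r$i2_cut)
    )
    g2 <- all(clauses2)
    assoc_ok <- if (identical(r$group1_rule, "point")) {
      p$or[i] >= d$or[i]
    } else {
      p$ci_hi[i] >= d$or[i]
    }
    clauses1 <- c(rare = maf_r < r$maf_rare, assoc = assoc_ok)
    g1 <- all(clauses1)
    if (g1 && g2) {
      warnf("variant %s satisfies both group definitions; left unclassified",
            tags[i])
      group <- "unclassified"
      prov <- "conflict: Group1 and Group2 clauses both satisfied"
    } else if (g1) {
      group <- "Group1"
      prov <- sprintf(
        "rare in replication (MAF %.4g < %.4g); replication %s (OR %.2f, CI %.2f-%.2f vs discovery OR %.2f)",
        maf_r, r$maf_rare,
        if (identical(r$group1_rule, "point")) "OR >= discovery OR"
        else "CI reaches discovery OR",
        p$or[i], p$ci_lo[i], p$ci_hi[i], d$or[i])
    } else if (g2) {
      group <- "Group2"
      prov <- sprintf(
        "common in replication (MAF %.3f > %.3f); null replication (p = %.3g > %.3g, OR %.2f < %.2f); meta %s",
        maf_r, maf_d, p$p[i], r$p_thresh, p$or[i], r$or_null,
        if (mm$i2[i] > r$i2_cut) sprintf("heterogeneous (I2 = %.1f > %g)",
                                         mm$i2[i], r$i2_cut)
        else sprintf("OR_fixed %.2f <= discovery OR %.2f", mm$or_fixed[i], d$or[i]))
    } else {
      group <- "unclassified"
      fired <- c(names(clauses1)[clauses1], names(clauses2)[clauses2])
      prov <- sprintf("no full clause set fired (partial: %s)",
                      if (length(fired)) paste(fired, collapse = ",") else "none")
    }
    data.frame(id = tags[i], group = group, provenance = prov,
               maf_disc = maf_d, maf_rep = maf_r,
               or_disc = d$or[i], or_rep = p$or[i], p_rep = p$p[i],
               or_fixed = mm$or_fixed[i], i2 = mm$i2[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "rules") <- r
  res
}

#' Split retained variants into regulatory (1A) and coding (1B) subgroups
#'
#' Group 1A: position inside the regulatory interval AND replication OR
#' strictly above `or_strong`. Group 1B: position inside the coding
#' interval. Variants in neither interval stay `Group1` with a warning
#' (coverage gap in the region map).
#'
#' @param group1 data.frame with `id`, `pos`, `or_rep` for the retained
#'   variants.
#' @param region_map an [annotation_track()]-like `GRanges` (or
#'   data.frame with `chrom`, `start`, `end` 0-based half-open and
#'   `name`) with intervals named `"regulatory"` and `"coding"`.
#' @param or_strong strong-association threshold (default 1.5, strict).
#' @param chrom chromosome of the variants.
#' @return `group1` with `subgroup` (`Group1A`/`Group1B`/`Group1`) and
#'   `provenance` columns added.
#' @export
subgroup_1A_1B <- function(group1, region_map, or_strong = 1.5,
                           chrom = NULL) {
  if (is.data.frame(region_map)) {
    region_map <- GenomicRanges::GRanges(
      region_map$chrom,
      IRanges::IRanges(region_map$start + 1L, region_map$end),
      name = region_map$name)
  }
  chrom <- chrom %||% as.character(GenomicRanges::seqnames(region_map)[1])
  vgr <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(group1$pos, width = 1L))
  in_region <- function(nm) {
    reg <- region_map[region_map$name == nm]
    IRanges::overlapsAny(vgr, reg)
  }
  in_reg <- in_region("regulatory")
  in_cod <- in_region("coding")
  sub <- character(nrow(group1))
  prov <- character(nrow(group1))
  for (i in seq_len(nrow(group1))) {
    if (in_reg[i] && group1$or_rep[i] > or_strong) {
      sub[i] <- "Group1A"
      prov[i] <- sprintf("regulatory interval, replication OR %.2f > %g",
                         group1$or_rep[i], or_strong)
    } else if (in_cod[i]) {
      sub[i] <- "Group1B"
      prov[i] <- "coding interval"
    } else if (in_reg[i]) {
      sub[i] <- "Group1"
      prov[i] <- sprintf("regulatory interval but replication OR %.2f <= %g",
                         group1$or_rep[i], or_strong)
    } else {
      sub[i] <- "Group1"
      warnf("variant %s lies outside both mapped regions; left unsubgrouped",
            group1$id[i])
      prov[i] <- "outside region map (coverage gap)"
    }
  }
  group1$subgroup <- sub
  group1$subgroup_provenance <- prov
  group1
}
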