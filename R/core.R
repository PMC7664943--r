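#' Cross-population core-haplotype intersection
#'
#' The core risk haplotype is the minimal alignment of the
#' per-population merged blocks containing the index variant: its
#' interval is the intersection of those block intervals and its
#' members are the tag-SNPs shared by every contributing population,
#' restricted to the interval. Populations in which the risk-allele
#' combination is rarer than `min_freq` are dropped from the
#' intersection (they carry no information about the shared haplotype)
#' and listed with a provenance note.
#'
#' @param per_pop named list (one entry per population) of lists with
#'   elements `block` (a merged-region row: `chrom`, `start_pos`,
#'   `end_pos` containing the index), `tags` (a [tag_snps()] result) and
#'   `risk_freq` (frequency of the risk-allele combination in that
#'   population).
#' @param index_variant index variant id (must be a member everywhere).
#' @param min_freq drop threshold for the risk-haplotype frequency
#'   (default 0.001, i.e. 0.1%).
#' @return a `core_haplotype` list: `chrom`, `start_pos`, `end_pos`,
#'   `members`, `span_bp`, `span_kb`, `populations`, `dropped`
#'   (data.frame population/frequency/note).
#' @export
intersect_core <- function(per_pop, index_variant, min_freq = 0.001) {
  stopifnot(length(per_pop) >= 1L)
  freqs <- vapply(per_pop, function(x) x$risk_freq %||% NA_real_, numeric(1))
  drop <- !is.na(freqs) & freqs < min_freq
  dropped <- data.frame(
    population = names(per_pop)[drop],
    risk_freq = freqs[drop],
    note = sprintf("risk-haplotype frequency %.4g < %.4g; excluded from intersection",
                   freqs[drop], min_freq),
    stringsAsFactors = FALSE
  )
  keep <- per_pop[!drop]
  if (!length(keep)) stopf("no shared core: every population was dropped")
  chroms <- vapply(keep, function(x) as.character(x$block$chrom), "")
  if (length(unique(chroms)) != 1L) stopf("blocks disagree on chromosome")
  start <- max(vapply(keep, function(x) x$block$start_pos, numeric(1)))
  end <- min(vapply(keep, function(x) x$block$end_pos, numeric(1)))
  if (start >= end) stopf("no shared core: block interval intersection is empty")
  member_sets <- lapply(keep, function(x) {
    m <- x$tags$members
    m$id[m$pos >= start & m$pos <= end]
  })
  members <- Reduce(intersect, member_sets)
  if (!index_variant %in% members) {
    stopf("index variant %s is not shared by all populations' tag sets",
          index_variant)
  }
  structure(list(
    chrom = chroms[1], start_pos = start, end_pos = end,
    members = members,
    span_bp = end - start,
    span_kb = round((end - start) / 1000, 1),
    populations = names(keep),
    dropped = dropped
  ), class = "core_haplotype")
}

#' @export
print.core_haplotype <- function(x, ...) {
  cat(sprintf("<core_haplotype> %s:%d-%d (%s kb), %d shared tags, pops: %s\n",
              x$chrom, x$start_pos, x$end_pos, format(x$span_kb),
              length(x$members), paste(x$populations, collapse = ", ")))
  if (nrow(x$dropped)) {
    cat("  dropped:", paste(x$dropped$population, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Interval span and reduction report
#'
#' Span arithmetic on `chrN:a-b` style 1-based boundary coordinates:
#' `span_bp = end - start` (the convention that reproduces published
#' kb figures for such intervals; the inclusive `end - start + 1`
#' alternative does not). Optionally reports the percentage reduction
#' against a wider reference interval.
#'
#' @param chrom chromosome label.
#' @param start,end boundary positions, `start < end`.
#' @param kb_precision decimals for the kb figure (default 0).
#' @param reference optional `c(start, end)` of the reference interval.
#' @return list: `chrom`, `start`, `end`, `span_bp`, `span_kb`, and
#'   `reduction_pct` when a reference is given.
#' @export
span_report <- function(chrom, start, end, kb_precision = 0,
                        reference = NULL) {
  if (start >= end) stopf("span requires start < end (got %s:%s-%s)",
                          chrom, format(start), format(end))
  span <- end - start
  out <- list(chrom = chrom, start = start, end = end,
              span_bp = span,
              span_kb = round(span / 1000, kb_precision))
  if (!is.null(reference)) {
    ref_span <- reference[2] - reference[1]
    if (ref_span <= 0) stopf("reference interval must have positive span")
    out$reduction_pct <- (ref_span - span) / ref_span * 100
  }
  out
}

#' Parse a "chrN:a-b" interval string
#'
#' @param x interval string, commas allowed in the numbers.
#' @return list `chrom`, `start`, `end`.
#' @export
parse_interval <- function(x) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^\\s*(\\S+):(\\d+)-(\\d+)\\s*$", x))[[1]]
  if (length(m) != 4L) stopf("cannot parse interval '%s'", x)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}
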