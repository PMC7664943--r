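#' Scored annotation track
#'
#' A set of scored genomic intervals of one declared feature class.
#' Constructor coordinates follow the BED convention (0-based half-open);
#' internally intervals are held as a `GRanges` (1-based closed) and all
#' overlap arithmetic goes through `IRanges`.
#'
#' @param feature_class one of `"dnase_hotspot"`, `"histone_signal_25bp"`,
#'   `"interaction_fragment"`, `"genehancer_element"`,
#'   `"segmentation_state"`.
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param score numeric score per interval (SignalValue, CHICAGO score,
#'   histone enrichment, ...).
#' @param name interval name (fragment id, segmentation state, ...).
#' @param cell_type cell-type label per interval (`NA` when not
#'   cell-resolved).
#' @return an `annotation_track`: a `GRanges` with `score`, `name`,
#'   `cell_type` metadata columns and the feature class in its metadata.
#' @export
annotation_track <- function(feature_class, chrom, start, end,
                             score = NA_real_, name = NA_character_,
                             cell_type = NA_character_) {
  classes <- c("dnase_hotspot", "histone_signal_25bp", "interaction_fragment",
               "genehancer_element", "segmentation_state")
  feature_class <- match.arg(feature_class, classes)
  if (any(end <= start)) stopf("track intervals must have end > start")
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = start, end = end,
                   score = rep_len(as.numeric(score), n),
                   name = rep_len(as.character(name), n),
                   cell_type = rep_len(as.character(cell_type), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end),
    score = df$score, name = df$name, cell_type = df$cell_type
  )
  if (feature_class == "histone_signal_25bp") {
    if (any(GenomicRanges::width(gr) != 25L)) {
      stopf("histone_signal_25bp intervals must be exactly 25 bp")
    }
    for (ct in unique(gr$cell_type)) {
      sub <- gr[gr$cell_type %in% ct]
      if (length(IRanges::findOverlaps(sub, drop.self = TRUE)) > 0) {
        stopf("histone_signal_25bp intervals overlap within cell type %s", ct)
      }
    }
  }
  S4Vectors::metadata(gr)$feature_class <- feature_class
  gr
}

track_class <- function(track) {
  S4Vectors::metadata(track)$feature_class
}

#' Write / read an annotation track as BED6+2
#'
#' Columns: chrom, start (0-based), end, name, score, strand, plus two
#' non-standard columns declaring the feature class and cell type.
#'
#' @param track an [annotation_track()].
#' @param path output path.
#' @export
write_track_bed <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    name = track$name,
    score = track$score,
    strand = ".",
    feature_class = track_class(track),
    cell_type = track$cell_type,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_track_bed
#' @export
read_track_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "feature_class", "cell_type"),
                   stringsAsFactors = FALSE, na.strings = c("NA", "."))
  fc <- unique(df$feature_class)
  if (length(fc) != 1L) stopf("%s mixes feature classes: %s",
                              path, paste(fc, collapse = ", "))
  annotation_track(fc, df$chrom, df$start, df$end,
                   score = df$score, name = df$name, cell_type = df$cell_type)
}

# variants as width-1 GRanges (1-based) for overlap arithmetic
variants_gr <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos, width = 1L),
                         id = variants$id)
}
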