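#' Generate annotation tracks and motif fixtures for a simulated panel
#'
#' Emits the annotation layers the prioritization stage consumes, with
#' signal planted over the designated functional variants only:
#' open-chromatin hotspots (SignalValue > 5 over functional variants,
#' background intervals < 2.5 over the rest), a contiguous 25-bp-binned
#' histone-signal track tiling the locus, chromatin-interaction fragments
#' covering the functional variants plus one distal "promoter" fragment,
#' and a reference-sequence window in which each functional variant sits
#' inside a planted 8-bp motif whose consensus is completed by the
#' alternate allele and disrupted by the reference allele.
#'
#' @param panel a [phased_panel()].
#' @param functional_set variant indices (or ids) designated functional.
#' @param seed integer seed.
#' @return list with elements `tracks` (named list of
#'   [annotation_track()]: `dnase`, `histone`, `interaction`), `refseq`
#'   (a `ref_window`), `pwms` (list of [pwm()]), and `motifs`
#'   (data.frame of planted placements).
#' @export
generate_tracks <- function(panel, functional_set, seed) {
  if (is.character(functional_set)) {
    functional_set <- match(functional_set, panel$variants$id)
    if (anyNA(functional_set)) stopf("unknown functional variant id")
  }
  m <- n_variants(panel)
  if (length(functional_set) &&
      (min(functional_set) < 1 || max(functional_set) > m)) {
    stopf("functional_set indices out of range")
  }
  v <- panel$variants
  chrom <- v$chrom[1]
  pos <- v$pos
  fpos <- pos[functional_set]
  if (length(fpos) > 1 && min(diff(sort(fpos))) < 29L) {
    stopf("planted motif windows for adjacent functional variants overlap")
  }
  locus0 <- (min(pos) - 200L) %/% 25L * 25L     # 0-based, 25-bp aligned
  locus1 <- ((max(pos) + 3200L) %/% 25L + 1L) * 25L

  with_seed(stage_seed(seed, "tracks"), {
    fun <- sort(functional_set)
    bgv <- setdiff(seq_len(m), fun)

    dnase <- annotation_track(
      "dnase_hotspot", chrom,
      start = c(pos[fun] - 50L, pos[bgv] - 30L),
      end = c(pos[fun] + 25L, pos[bgv] + 10L),
      score = c(runif(length(fun), 5.5, 9), runif(length(bgv), 0.5, 2.4)),
      name = c(sprintf("hs_%s", v$id[fun]), sprintf("bg_%s", v$id[bgv])),
      cell_type = "Th1"
    )

    bins <- seq(locus0, locus1 - 25L, by = 25L)
    val <- runif(length(bins), 0.2, 2)
    hit_bin <- findInterval(pos[fun] - 1L, bins)
    val[hit_bin] <- runif(length(hit_bin), 6, 9)
    histone <- annotation_track("histone_signal_25bp", chrom,
                                start = bins, end = bins + 25L,
                                score = val,
                                name = sprintf("bin%05d", seq_along(bins)),
                                cell_type = "GM12878")

    frag_start <- c(pos[fun] - 40L, max(pos) + 1000L)
    frag_end <- c(pos[fun] + 40L, max(pos) + 3000L)
    frag_name <- c(sprintf("frag_%s", v$id[fun]), "promoter_frag")
    cell_types <- c("tB", "nCD4")
    interaction <- annotation_track(
      "interaction_fragment", chrom,
      start = rep(frag_start, each = length(cell_types)),
      end = rep(frag_end, each = length(cell_types)),
      score = as.vector(vapply(
        seq_along(frag_start),
        function(i) c(runif(1, 5.6, 15), runif(1, 0.5, 5)), numeric(2))),
      name = rep(frag_name, each = length(cell_types)),
      cell_type = rep_len(cell_types, 2L * length(frag_start))
    )

    # reference window with planted motifs (variant at motif offset 4)
    seq_len_bp <- locus1 - locus0
    bases <- c("A", "C", "G", "T")
    seq_chr <- sample(bases, seq_len_bp, replace = TRUE)
    seq_chr[pos - locus0] <- v$ref                # reference carries REF
    pwms <- list()
    motifs <- data.frame()
    for (k in seq_along(fun)) {
      j <- fun[k]
      consensus <- sample(bases, 8L, replace = TRUE)
      consensus[4L] <- v$alt[j]                   # alt completes the motif
      mstart <- pos[j] - locus0 - 3L              # motif base 1, in window
      idx <- mstart + 0:7
      seq_chr[idx] <- consensus
      seq_chr[pos[j] - locus0] <- v$ref[j]        # ref disrupts column 4
      name <- sprintf("TF%02d_sim%d", k, k)
      pwms[[name]] <- consensus_pwm(name, consensus)
      motifs <- rbind(motifs, data.frame(
        variant = v$id[j], motif = name,
        consensus = paste(consensus, collapse = ""),
        start0 = locus0 + mstart - 1L, stringsAsFactors = FALSE))
    }
    refseq <- ref_window(chrom, locus0,
                         Biostrings::DNAString(paste(seq_chr, collapse = "")))
    list(tracks = list(dnase = dnase, histone = histone,
                       interaction = interaction),
         refseq = refseq, pwms = pwms, motifs = motifs)
  })
}

#' Reference sequence window
#'
#' A chromosome subsequence anchored at a genomic offset: base `i` of
#' `seq` sits at 1-based genomic position `offset + i`.
#'
#' @param chrom chromosome label.
#' @param offset 0-based genomic offset of the window start.
#' @param seq a `Biostrings::DNAString`.
#' @export
ref_window <- function(chrom, offset, seq) {
  structure(list(chrom = chrom, offset = as.integer(offset),
                 seq = Biostrings::DNAString(seq)),
            class = "ref_window")
}

#' @export
print.ref_window <- function(x, ...) {
  cat(sprintf("<ref_window> %s:%d-%d (%d bp)\n", x$chrom, x$offset + 1L,
              x$offset + length(x$seq), length(x$seq)))
  invisible(x)
}

#' Write / read a reference window as FASTA
#'
#' The record name encodes the anchor as `chrom:start-end` (1-based).
#'
#' @param rw a [ref_window()].
#' @param path file path.
#' @export
write_ref_fasta <- function(rw, path) {
  ss <- Biostrings::DNAStringSet(rw$seq)
  names(ss) <- sprintf("%s:%d-%d", rw$chrom, rw$offset + 1L,
                       rw$offset + length(rw$seq))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_ref_fasta
#' @export
read_ref_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)[1]
  parts <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)", nm))[[1]]
  if (length(parts) != 4L) stopf("FASTA name '%s' lacks a chrom:start-end anchor", nm)
  ref_window(parts[2], as.integer(parts[3]) - 1L, ss[[1]])
}
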