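#' Position weight matrix
#'
#' Column-stochastic motif model over A/C/G/T with pseudocount
#' smoothing; scores are log2 odds against the background (uniform 0.25
#' by default, the convention of the HaploReg-style annotations this
#' package emulates).
#'
#' @param name motif name; the token before the first underscore is
#'   treated as the TF family (e.g. `"RXRA"` from `"RXRA_disc4"`).
#' @param matrix `L x 4` numeric matrix of column probabilities
#'   (columns A, C, G, T); rows are renormalized after smoothing.
#' @param background length-4 background distribution (default uniform).
#' @param pseudocount smoothing mass added to every entry (default
#'   0.001) so all entries are positive.
#' @return a `pwm` object.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4),
                pseudocount = 0.001) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stopf("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4L) stopf("PWM must have length >= 4")
  if (any(matrix < 0)) stopf("PWM probabilities must be nonnegative")
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    stopf("each PWM column distribution must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stopf("background must be a positive distribution summing to 1")
  }
  m <- matrix + pseudocount
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = m, background = background,
                 length = nrow(m),
                 family = sub("_.*$", "", name)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$matrix, 1L, which.max)],
                collapse = "")
  cat(sprintf("<pwm> %s (family %s), length %d, consensus %s\n",
              x$name, x$family, x$length, cons))
  invisible(x)
}

#' A near-deterministic PWM from a consensus sequence
#'
#' @param name motif name.
#' @param consensus character vector of bases or a single string.
#' @param p_consensus probability mass on the consensus base per column.
#' @export
consensus_pwm <- function(name, consensus, p_consensus = 0.97) {
  if (length(consensus) == 1L && nchar(consensus) > 1L) {
    consensus <- strsplit(consensus, "")[[1]]
  }
  bases <- c("A", "C", "G", "T")
  m <- matrix((1 - p_consensus) / 3, length(consensus), 4,
              dimnames = list(NULL, bases))
  for (i in seq_along(consensus)) m[i, consensus[i]] <- p_consensus
  pwm(name, m)
}

# per-column log2-odds score table (L x 4)
pwm_score_table <- function(p) {
  log2(p$matrix / rep(p$background, each = p$length))
}

#' Stringency threshold of a PWM score distribution
#'
#' The smallest attainable score `s` such that
#' `P(score >= s) <= p_value` for a random sequence drawn from the
#' background. Computed by exact enumeration of all `4^L` sequences
#' when `4^L <= 65536`, otherwise by exact dynamic programming
#' (convolution) over the per-column score distribution discretized to
#' `bin` log2 units. If even the maximal score has tail probability
#' above `p_value` the threshold is unattainable (`Inf`,
#' `attainable = FALSE`).
#'
#' @param pwm a [pwm()].
#' @param p_value tail probability (default `4^-8`, the conventional
#'   single-motif stringency).
#' @param method `"auto"`, `"enumerate"` or `"dp"`.
#' @param bin score discretization width (default 0.01).
#' @return list: `threshold`, `attainable`, `p_value`, `method`.
#' @export
pwm_score_threshold <- function(pwm, p_value = 4^-8,
                                method = c("auto", "enumerate", "dp"),
                                bin = 0.01) {
  method <- match.arg(method)
  if (p_value <= 0 || p_value >= 1) stopf("p_value must be in (0, 1)")
  L <- pwm$length
  if (method == "auto") {
    method <- if (4^L <= 65536) "enumerate" else "dp"
  }
  # integer-binned per-column scores; both routes share the binning so
  # the DP is exactly the distribution of the binned enumeration
  sc <- round(pwm_score_table(pwm) / bin)
  bg <- pwm$background
  if (method == "enumerate") {
    tot <- numeric(1)
    scores <- 0
    probs <- 1
    for (i in seq_len(L)) {
      scores <- as.vector(outer(scores, sc[i, ], `+`))
      probs <- as.vector(outer(probs, bg, `*`))
    }
    agg <- tapply(probs, scores, sum)
  } else {
    dist <- c(`0` = 1)
    for (i in seq_len(L)) {
      keys <- as.vector(outer(as.numeric(names(dist)), sc[i, ], `+`))
      vals <- as.vector(outer(as.numeric(dist), bg, `*`))
      dist <- tapply(vals, keys, sum)
    }
    agg <- dist
  }
  s <- as.numeric(names(agg))
  ord <- order(s)
  s <- s[ord]
  pr <- as.numeric(agg)[ord]
  tail <- rev(cumsum(rev(pr)))
  ok <- which(tail <= p_value * (1 + 1e-12))
  if (!length(ok)) {
    return(list(threshold = Inf, attainable = FALSE, p_value = p_value,
                method = method))
  }
  list(threshold = s[ok[1]] * bin, attainable = TRUE, p_value = p_value,
       method = method)
}

#' Write / read motifs in minimal MEME text format
#'
#' @param pwms list of [pwm()] objects.
#' @param path file path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$length), con)
    writeLines(apply(p$matrix, 1L, function(r) {
      sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    nums <- as.numeric(regmatches(lines[bgi + 1L],
                                  gregexpr("[0-9.]+", lines[bgi + 1L]))[[1]])
    if (length(nums) == 4L) bg <- nums
  }
  starts <- grep("^MOTIF ", lines)
  pwms <- list()
  for (s in starts) {
    name <- strsplit(sub("^MOTIF +", "", lines[s]), "[ \t]")[[1]][1]
    wi <- grep("letter-probability matrix", lines[seq(s, length(lines))])[1] + s - 1L
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[wi]))
    rows <- lines[(wi + 1L):(wi + w)]
    m <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])
    }))
    # re-normalize away printed rounding before validation
    m <- m / rowSums(m)
    pwms[[name]] <- pwm(name, m, background = bg, pseudocount = 0.001)
  }
  pwms
}
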