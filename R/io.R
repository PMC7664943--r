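#' Write a phased panel as VCF v4.2
#'
#' One file per panel; genotypes are emitted phased (`0|1`), missing
#' calls as `.|.`.
#'
#' @param panel a [phased_panel()].
#' @param path output path (plain-text `.vcf`).
#' @param sample_ids optional sample names (default `S00001`...).
#' @export
write_panel_vcf <- function(panel, path, sample_ids = NULL) {
  n <- n_samples(panel)
  sample_ids <- sample_ids %||% sprintf("S%05d", seq_len(n))
  h <- panel$haplotypes
  a1 <- h[2L * seq_len(n) - 1L, , drop = FALSE]
  a2 <- h[2L * seq_len(n), , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2)),
               nrow = n)
  v <- panel$variants
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a phased panel
#'
#' Parses GT fields via `vcfR`; `|` separators are honored as phased,
#' `/` genotypes are accepted (their within-sample order is arbitrary,
#' so downstream phase-sensitive operations should be run with
#' `phased = FALSE`).
#'
#' @param path VCF path.
#' @param population population label for all samples (or a vector).
#' @param phenotype optional phenotype vector (1/2/`NA`) or a
#'   [read_phenotypes()] frame matched by sample id.
#' @return a [phased_panel()].
#' @export
read_panel_vcf <- function(path, population = "pop", phenotype = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  n <- length(samples)
  m <- nrow(variants)
  hap <- matrix(NA_integer_, 2L * n, m)
  alleles <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  to_int <- function(x) suppressWarnings(as.integer(x))
  hap[2L * seq_len(n) - 1L, ] <- t(matrix(to_int(alleles), nrow = m))
  hap[2L * seq_len(n), ] <- t(matrix(to_int(alleles2), nrow = m))
  pop <- rep_len(population, n)
  ph <- rep(NA_integer_, n)
  if (is.data.frame(phenotype)) {
    ph <- phenotype$status[match(samples, phenotype$sample)]
  } else if (!is.null(phenotype)) {
    ph <- rep_len(as.integer(phenotype), n)
  }
  phased_panel(variants, hap, pop, ph)
}

#' Write / read a phenotype table
#'
#' Tab-separated columns `sample`, `population`, `status` (1 = control,
#' 2 = case).
#'
#' @param panel a [phased_panel()].
#' @param path file path.
#' @param sample_ids optional sample names (must match the VCF).
#' @export
write_phenotypes <- function(panel, path, sample_ids = NULL) {
  n <- n_samples(panel)
  sample_ids <- sample_ids %||% sprintf("S%05d", seq_len(n))
  df <- data.frame(sample = sample_ids, population = panel$population,
                   status = panel$phenotype, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
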