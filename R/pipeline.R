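#' Pipeline configuration
#'
#' Collects every stage threshold, the input description (either a
#' [sim_config()] to simulate from, or file paths), and the run seed.
#' The configuration is echoed (with its hash) into every output.
#'
#' @param sim a [sim_config()] to simulate inputs from, or `NULL`.
#' @param inputs list of file paths when not simulating: `vcf` (named
#'   character vector, one per population; the first is the discovery
#'   ancestry and the last the replication ancestry), `phenotypes`
#'   (TSV), `tracks` (named BED paths: dnase/histone/interaction/...),
#'   `fasta`, `meme`, optional `eqtl` (TSV id/eqtl) and `region_map`
#'   (BED with regulatory/coding intervals).
#' @param out_dir directory for per-stage TSVs, the JSON summary and
#'   the log (`NULL` = keep results in memory only).
#' @param seed run seed; every stochastic stage derives its stream from
#'   it.
#' @param ... threshold overrides: `spine_dprime` (0.8),
#'   `interblock_dprime` (0.75), `tag_r2` (0.75), `maf_min` (0.01),
#'   `hwe_p_min` (1e-4), `call_rate_min` (0.75), `p_thresh` (0.01),
#'   `maf_rare` (0.01), `or_strong` (1.5), `i2_cut` (50),
#'   `min_core_freq` (0.001), `dnase_tiers` (c(2.5, 5)),
#'   `interaction_min_score` (5), `astf_stringency` (4^-8),
#'   `astf_min_delta` (2), `kb_precision` (1), `group1_rule` ("ci").
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL, out_dir = NULL,
                            seed = 1L, ...) {
  th <- modifyList(list(
    spine_dprime = 0.8, interblock_dprime = 0.75, tag_r2 = 0.75,
    maf_min = 0.01, hwe_p_min = 1e-4, call_rate_min = 0.75,
    p_thresh = 0.01, maf_rare = 0.01, or_strong = 1.5, i2_cut = 50,
    min_core_freq = 0.001, dnase_tiers = c(2.5, 5),
    interaction_min_score = 5, astf_stringency = 4^-8,
    astf_min_delta = 2, kb_precision = 1, group1_rule = "ci"
  ), list(...))
  if (is.null(sim) && is.null(inputs)) {
    stopf("pipeline_config needs either a sim_config or input paths")
  }
  structure(list(sim = sim, inputs = inputs, out_dir = out_dir,
                 seed = as.integer(seed), thresholds = th),
            class = "pipeline_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    panels <- simulate_panel(sim)
    panels <- lapply(panels, assign_phenotypes,
                     causal_variant = sim$causal_variant,
                     causal_or = sim$causal_or,
                     case_fraction = sim$case_fraction,
                     seed = stage_seed(config$seed, "phenotypes"))
    fx <- generate_tracks(panels[[1]], sim$functional_set,
                          seed = stage_seed(config$seed, "fixtures"))
    list(panels = panels, tracks = fx$tracks, refseq = fx$refseq,
         pwms = fx$pwms, index = attr(panels, "truth")$index_id %||%
           panels[[1]]$variants$id[sim$index_variant],
         eqtl = NULL, region_map = NULL)
  } else {
    inp <- config$inputs
    paths <- c(inp$vcf, inp$phenotypes, unlist(inp$tracks), inp$fasta,
               inp$meme, inp$eqtl, inp$region_map)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stopf("missing input file(s): %s", paste(missing, collapse = ", "))
    }
    pheno <- if (!is.null(inp$phenotypes)) read_phenotypes(inp$phenotypes)
    panels <- lapply(names(inp$vcf), function(nm) {
      read_panel_vcf(inp$vcf[[nm]], population = nm, phenotype = pheno)
    })
    names(panels) <- names(inp$vcf)
    tracks <- lapply(inp$tracks, read_track_bed)
    eqtl <- if (!is.null(inp$eqtl)) read.table(inp$eqtl, header = TRUE,
                                               sep = "\t",
                                               stringsAsFactors = FALSE)
    region_map <- if (!is.null(inp$region_map)) {
      df <- read.table(inp$region_map, sep = "\t", header = FALSE,
                       col.names = c("chrom", "start", "end", "name"),
                       stringsAsFactors = FALSE)
      GenomicRanges::GRanges(df$chrom,
                             IRanges::IRanges(df$start + 1L, df$end),
                             name = df$name)
    }
    list(panels = panels,
         tracks = tracks,
         refseq = if (!is.null(inp$fasta)) read_ref_fasta(inp$fasta),
         pwms = if (!is.null(inp$meme)) read_meme(inp$meme),
         index = inp$index_variant %||%
           stopf("inputs must name index_variant"),
         eqtl = eqtl, region_map = region_map)
  }
}

#' Run the full refinement and prioritization pipeline
#'
#' Chains simulate/load -> QC -> solid-spine blocks -> block merging ->
#' tag selection -> cross-population core intersection -> per-ancestry
#' association -> meta-analysis -> trans-ancestral exclusion mapping ->
#' annotation overlap -> allele-specific TF scan -> layered
#' prioritization -> report. The first population is the discovery
#' ancestry, the last the replication ancestry. Block and tag
#' derivation run on fully QC-filtered genotypes; association and
#' exclusion mapping use the call-rate rule only, so rare replication
#' alleles stay observable. Deterministic under the config seed; each
#' stage logs its record counts and any stage failure halts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list): `qc`, `blocks`, `merged`, `tags`,
#'   `core`, `association`, `meta`, `groups`, `priority`, `astf`,
#'   `span`, `summary` (the JSON-ready list), `log` (character).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  inp <- stage("inputs", pipeline_inputs(config))
  panels <- inp$panels
  if (length(panels) < 2L) {
    stopf("pipeline stage 'inputs' failed: need >= 2 populations (discovery + replication)")
  }
  pops <- names(panels)
  disc <- pops[1]
  repl <- pops[length(pops)]
  index <- inp$index
  note("inputs: %d populations (%s), %d variants, index %s",
       length(panels), paste(pops, collapse = ", "),
       n_variants(panels[[1]]), index)

  qc <- stage("qc", lapply(panels, qc_filter, maf_min = th$maf_min,
                           hwe_p_min = th$hwe_p_min,
                           call_rate_min = th$call_rate_min))
  for (p in pops) {
    rep_ <- qc[[p]]$report
    note("qc[%s]: %d in = %d retained + %d dropped (%s)", p, nrow(rep_),
         sum(rep_$pass), sum(!rep_$pass),
         paste(sprintf("%s:%d", names(table(rep_$reason)),
                       as.integer(table(rep_$reason))), collapse = ", "))
  }

  per_pop <- list()
  blocks_all <- list()
  merged_all <- list()
  tags_all <- list()
  for (p in pops) {
    panel_p <- qc[[p]]$panel
    blocks <- stage(paste0("blocks[", p, "]"),
                    solid_spine_blocks(panel_p, spine_dprime = th$spine_dprime))
    blocks$population <- p
    merged <- stage(paste0("merge[", p, "]"),
                    merge_blocks(blocks, panel_p,
                                 interblock_dprime = th$interblock_dprime))
    idx_pos <- panels[[p]]$variants$pos[match(index, panels[[p]]$variants$id)]
    row <- which(merged$start_pos <= idx_pos & merged$end_pos >= idx_pos)
    if (!length(row)) {
      stopf("pipeline stage 'merge[%s]' failed: no merged block contains the index variant", p)
    }
    tags <- stage(paste0("tags[", p, "]"),
                  tag_snps(panel_p, index, r2_threshold = th$tag_r2,
                           qc_report = qc[[p]]$report))
    risk_map <- setNames(
      panels[[disc]]$variants$alt[match(tags$members$id,
                                        panels[[disc]]$variants$id)],
      tags$members$id)
    rf <- if (p == disc) {
      risk_haplotype_frequency(panels[[disc]], risk_map)
    } else {
      shared <- risk_map[names(risk_map) %in% panels[[p]]$variants$id]
      risk_haplotype_frequency(panels[[p]], shared)
    }
    per_pop[[p]] <- list(block = merged[row[1], ], tags = tags,
                         risk_freq = rf$frequency)
    blocks_all[[p]] <- blocks
    merged_all[[p]] <- merged
    tags_all[[p]] <- tags
    note("blocks[%s]: %d blocks -> %d merged regions; %d tags; risk-hap freq %.4f",
         p, nrow(blocks), nrow(merged), nrow(tags$members), rf$frequency)
  }

  core <- stage("refine", intersect_core(per_pop, index,
                                         min_freq = th$min_core_freq))
  note("refine: core %s:%d-%d (%d bp), %d shared tags; dropped: %s",
       core$chrom, core$start_pos, core$end_pos, core$span_bp,
       length(core$members),
       if (nrow(core$dropped)) paste(core$dropped$population, collapse = ",")
       else "none")

  # classify the discovery tag-SNPs that fall inside the shared core
  # interval (the replication ancestry supplies MAF/OR for each of them,
  # whether or not it tags the risk haplotype there)
  disc_tags <- per_pop[[disc]]$tags$members
  core_ids <- disc_tags$id[disc_tags$pos >= core$start_pos &
                             disc_tags$pos <= core$end_pos]
  assoc <- list()
  for (p in c(disc, repl)) {
    keep <- intersect(core_ids, panels[[p]]$variants$id)
    sub <- subset_panel(panels[[p]], variants = keep)
    assoc[[p]] <- stage(paste0("associate[", p, "]"),
                        allelic_association(sub, ancestry = p))
  }
  note("associate: %d core tags tested in %s and %s",
       nrow(assoc[[disc]]), disc, repl)

  meta <- stage("meta", meta_analyze(rbind(assoc[[disc]], assoc[[repl]])))
  groups <- stage("exclude", exclusion_mapping(
    intersect(core_ids, meta$id), assoc[[disc]], assoc[[repl]], meta,
    rules = list(p_thresh = th$p_thresh, maf_rare = th$maf_rare,
                 i2_cut = th$i2_cut, index_variant = index,
                 group1_rule = th$group1_rule)))
  note("exclude: %s", paste(sprintf("%s:%d", names(table(groups$group)),
                                    as.integer(table(groups$group))),
                            collapse = ", "))
  if (!is.null(inp$region_map)) {
    g1 <- groups[groups$group == "Group1", ]
    if (nrow(g1)) {
      g1$pos <- panels[[disc]]$variants$pos[match(g1$id,
                                                  panels[[disc]]$variants$id)]
      groups_sub <- subgroup_1A_1B(g1, inp$region_map,
                                   or_strong = th$or_strong)
      groups$subgroup <- groups_sub$subgroup[match(groups$id, groups_sub$id)]
    }
  }

  core_variants <- panels[[disc]]$variants[
    panels[[disc]]$variants$id %in% core_ids, , drop = FALSE]
  astf <- stage("astf", if (!is.null(inp$refseq) && length(inp$pwms)) {
    allele_specific_hits(core_variants, inp$pwms, inp$refseq,
                         min_abs_delta = th$astf_min_delta,
                         stringency_p = th$astf_stringency)
  } else {
    allele_specific_hits(core_variants, list(), inp$refseq)
  })
  priority <- stage("prioritize", prioritize(
    core_variants, inp$tracks, astf,
    thresholds = list(dnase_tiers = th$dnase_tiers,
                      interaction_min_score = th$interaction_min_score,
                      eqtl_flags = inp$eqtl)))
  note("prioritize: %d candidates of %d core tags",
       sum(priority$candidate), nrow(priority))

  ext_block <- per_pop[[disc]]$block
  span <- stage("span", span_report(
    core$chrom, core$start_pos, core$end_pos,
    kb_precision = th$kb_precision,
    reference = c(ext_block$start_pos, ext_block$end_pos)))
  note("span: core %d bp (%.1f kb), %.1f%% reduction vs discovery region %d bp",
       span$span_bp, span$span_kb, span$reduction_pct,
       ext_block$end_pos - ext_block$start_pos)

  summary <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    populations = pops,
    discovery = disc, replication = repl,
    index_variant = index,
    core = list(chrom = core$chrom, start = core$start_pos,
                end = core$end_pos, span_bp = span$span_bp,
                span_kb = span$span_kb,
                reduction_pct = span$reduction_pct,
                n_members = length(core$members),
                members = core$members,
                dropped_populations = core$dropped$population),
    group_counts = as.list(table(groups$group)),
    candidates = priority$id[priority$candidate],
    n_astf_hits = nrow(astf)
  )

  bundle <- list(
    qc = lapply(qc, `[[`, "report"), blocks = blocks_all,
    merged = merged_all, tags = tags_all, core = core,
    association = assoc, meta = meta, groups = groups,
    astf = astf, priority = priority, span = span,
    summary = summary, log = log
  )
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir, config)
  }
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- function(path) {
    cat(sprintf("# config_hash: %s\n", hash), file = path)
    path
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    stamp(path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
  }
  for (p in names(bundle$qc)) tsv(bundle$qc[[p]], sprintf("qc_%s.tsv", p))
  for (p in names(bundle$merged)) {
    df <- bundle$merged[[p]]
    df$members <- vapply(df$members, paste, "", collapse = ",")
    df$block_rows <- NULL
    tsv(df, sprintf("merged_blocks_%s.tsv", p))
  }
  for (p in names(bundle$association)) {
    tsv(bundle$association[[p]], sprintf("association_%s.tsv", p))
  }
  tsv(bundle$meta, "meta.tsv")
  tsv(bundle$groups, "groups.tsv")
  tsv(bundle$astf, "astf_hits.tsv")
  tsv(as.data.frame(bundle$priority), "priority.tsv")
  writeLines(jsonlite::toJSON(bundle$summary, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "summary.json"))
  writeLines(bundle$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
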