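## End-to-end orchestration: simulate -> consensus -> annotate -> diff ->
## integrate, with a machine-readable run report.

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with every numeric constant of
#' the analysis: consensus overlap fraction, target-window sizes, TSS bin
#' half-width, promoter span, significance and fold-change thresholds
#' (genes 0.6, regions 0.5, and no fold-change cutoff for the
#' genotype-dependence contrast), cluster counts (7 expression clusters,
#' 4 accessibility clusters) and the expression floor.
#'
#' @param synth A [shadeSimConfig()] list.
#' @param min_frac Consensus overlap fraction, in (0, 1].
#' @param window_up,window_down TF target window (bp 5' of TSS / 3' of TES).
#' @param tss_halfwidth Half-width of the TSS distance bin (bp).
#' @param promoter_bp Promoter span 5' of the TSS (bp).
#' @param alpha FDR threshold.
#' @param lfc_gene,lfc_region Absolute log2 fold-change thresholds.
#' @param k_deg,k_dar Cluster counts for expression / accessibility.
#' @param expressed_min_tpm Expression floor (mean TPM, wild type).
#' @param seed Default RNG seed for [runShadePipeline()].
#' @return A validated configuration list of class `shadePipelineConfig`.
#' @export
shadePipelineConfig <- function(synth = shadeSimConfig(),
                                min_frac = 0.5,
                                window_up = 3000, window_down = 1000,
                                tss_halfwidth = 100, promoter_bp = 2000,
                                alpha = 0.05,
                                lfc_gene = 0.6, lfc_region = 0.5,
                                k_deg = 7L, k_dar = 4L,
                                expressed_min_tpm = 1,
                                seed = 1L) {
  cfg <- list(synth = synth, min_frac = min_frac, window_up = window_up,
              window_down = window_down, tss_halfwidth = tss_halfwidth,
              promoter_bp = promoter_bp, alpha = alpha,
              lfc_gene = lfc_gene, lfc_region = lfc_region,
              k_deg = as.integer(k_deg), k_dar = as.integer(k_dar),
              expressed_min_tpm = expressed_min_tpm,
              seed = as.integer(seed))
  if (cfg$min_frac <= 0 || cfg$min_frac > 1) stop("min_frac must be in (0, 1]")
  pos <- c(cfg$window_up, cfg$window_down, cfg$tss_halfwidth,
           cfg$promoter_bp, cfg$alpha, cfg$k_deg, cfg$k_dar)
  if (any(pos <= 0)) stop("pipeline constants must be positive")
  if (cfg$alpha >= 1) stop("alpha must be below 1")
  if (cfg$lfc_gene < 0 || cfg$lfc_region < 0)
    stop("fold-change thresholds must be non-negative")
  class(cfg) <- "shadePipelineConfig"
  cfg
}

#' Serialise / restore a pipeline configuration (YAML)
#'
#' @param cfg A [shadePipelineConfig()] list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  named_to_map <- function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  synth <- lapply(unclass(cfg$synth), named_to_map)
  out <- lapply(unclass(cfg), named_to_map)
  out$synth <- synth
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- do.call(shadeSimConfig, lapply(raw$synth, function(x)
    if (is.list(x)) unlist(x) else x))
  raw$synth <- synth
  do.call(shadePipelineConfig, raw)
}

.samplesOf <- function(design, genotype, condition) {
  design$sample_id[design$genotype == genotype &
                     design$condition == condition]
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- expr
  message(sprintf("[chromShade] %-12s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full shade-response pipeline on simulated data
#'
#' Executes simulation, consensus building and filtering, open/closed
#' classification, TF target calling, gene and region differential testing,
#' direct-target intersection, and accessibility/expression clustering, in a
#' fixed order from one seeded RNG. All intermediates are written under
#' `out_dir` and a JSON run report (with a config hash) is produced;
#' identical configuration and seed give identical reports.
#'
#' @param cfg A [shadePipelineConfig()] list.
#' @param out_dir Output directory.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return Invisibly, a list with the `report` (also written to
#'   `report.json`), the [ShadeSim-class] object, and the main intermediate
#'   objects (`consensus`, `accessibility`, `targets`, `deg`, `dar`,
#'   `integration`, `clusters`).
#' @export
runShadePipeline <- function(cfg = shadePipelineConfig(), out_dir,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "shadePipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- .stage("simulate", simulateShadeExperiment(cfg$synth, seed))
  writeSimFixtures(sim, file.path(out_dir, "sim"))
  genes <- simGenes(sim)
  design <- simDesign(sim)

  ## consensus accessible chromatin
  cons <- .stage("consensus", {
    raw <- buildConsensus(simPeaks(sim), min_frac = cfg$min_frac)
    filterConsensus(raw, simBlacklist(sim))
  })
  cons_gr <- consensusRanges(cons)
  n_cons_raw <- length(buildConsensus(simPeaks(sim),
                                      min_frac = cfg$min_frac))
  cbed <- cons_gr
  cbed$score <- cbed$n_replicates_supporting
  writeBed(cbed, file.path(out_dir, "consensus.bed"))

  ## open/closed TF binding sites and promoter-proximality
  access <- classifyAccessibility(simTfPeaks(sim), cons)
  cons_ann <- nearestTss(cons_gr, genes)
  prom <- cons_ann$signed_distance >= -cfg$promoter_bp &
    cons_ann$signed_distance < 0
  pct_promoter <- 100 * mean(prom)

  ## map consensus regions onto the counting bins of the region count matrix
  bins <- SummarizedExperiment::rowRanges(simRegionCounts(sim))
  h <- findOverlaps(cons_gr, bins, ignore.strand = TRUE)
  ov <- width(pintersect(cons_gr[queryHits(h)], bins[subjectHits(h)]))
  best <- tapply(seq_along(ov), queryHits(h),
                 function(i) subjectHits(h)[i[which.max(ov[i])]])
  map <- data.frame(consensus = names(cons_gr)[as.integer(names(best))],
                    region_id = bins$region_id[as.integer(best)])
  region_counts <- assay(simRegionCounts(sim))[map$region_id, , drop = FALSE]
  dar_ranges <- cons_gr[map$consensus]
  names(dar_ranges) <- map$region_id

  ## differential expression
  gene_counts <- assay(simGeneCounts(sim))
  deg <- .stage("diff genes", {
    f <- sizeFactors(gene_counts)
    groups <- interaction(design$genotype, design$condition, drop = TRUE)
    phi <- estimateDispersions(gene_counts, groups, f)$tagwise
    run <- function(A, B) nbTest(gene_counts, A, B, f, phi)
    wt_h <- .samplesOf(design, "WT", "HRFR")
    wt1 <- .samplesOf(design, "WT", "LRFR_1h")
    wt25 <- .samplesOf(design, "WT", "LRFR_25h")
    mut_h <- .samplesOf(design, "tf_mutant", "HRFR")
    mut1 <- .samplesOf(design, "tf_mutant", "LRFR_1h")
    list(factors = f, dispersions = phi,
         wt_1h = run(wt_h, wt1), wt_25h = run(wt_h, wt25),
         genotype_1h = run(mut1, wt1),      # up = higher in wild type
         mut_1h = run(mut_h, mut1))
  })
  calls <- list(
    wt_1h = callSignificant(deg$wt_1h, cfg$alpha, cfg$lfc_gene),
    wt_25h = callSignificant(deg$wt_25h, cfg$alpha, cfg$lfc_gene),
    genotype_1h = callSignificant(deg$genotype_1h, cfg$alpha, 0),
    mut_1h = callSignificant(deg$mut_1h, cfg$alpha, cfg$lfc_gene))
  deg_up <- sort(union(calls$wt_1h$up, calls$wt_25h$up))
  deg_down <- sort(union(calls$wt_1h$down, calls$wt_25h$down))
  deg_union <- sort(union(deg_up, deg_down))

  ## TF targets and direct targets
  targets <- callTargets(simTfPeaks(sim), genes, cfg$window_up,
                         cfg$window_down)
  target_set <- targets$gene_id[targets$bound]
  direct <- directTargets(calls$genotype_1h$up, calls$genotype_1h$down,
                          target_set)

  ## expression clustering over genotype x condition mean TPM
  tpm <- tpmMatrix(gene_counts, width(genes))
  grp <- interaction(design$genotype, design$condition, drop = TRUE)
  cond_means <- vapply(split(design$sample_id, grp), function(sm)
    rowMeans(tpm[, sm, drop = FALSE]), numeric(nrow(tpm)))
  deg_clusters <- if (length(deg_union) >= cfg$k_deg)
    hclusterRows(rowZscore(cond_means[deg_union, , drop = FALSE]),
                 cfg$k_deg) else NULL

  ## differential accessibility
  dar <- .stage("diff regions", {
    f <- sizeFactors(region_counts)
    groups <- interaction(design$genotype, design$condition, drop = TRUE)
    phi <- estimateDispersions(region_counts, groups, f)$tagwise
    wt_h <- .samplesOf(design, "WT", "HRFR")
    list(factors = f, dispersions = phi,
         wt_1h = nbTest(region_counts, wt_h,
                        .samplesOf(design, "WT", "LRFR_1h"), f, phi),
         wt_25h = nbTest(region_counts, wt_h,
                         .samplesOf(design, "WT", "LRFR_25h"), f, phi))
  })
  dar_calls <- list(
    wt_1h = callSignificant(dar$wt_1h, cfg$alpha, cfg$lfc_region),
    wt_25h = callSignificant(dar$wt_25h, cfg$alpha, cfg$lfc_region))
  dar_1h <- union(dar_calls$wt_1h$up, dar_calls$wt_1h$down)
  dar_25h <- union(dar_calls$wt_25h$up, dar_calls$wt_25h$down)
  dar_union <- sort(union(dar_1h, dar_25h))

  ## integrate accessibility with expression
  integ <- .stage("integrate", if (length(dar_union) == 0) NULL else {
    dgr <- dar_ranges[dar_union]
    tab <- buildIntegrationTable(dgr, genes, tpm, design,
                                 deg_sets = list(up = deg_up,
                                                 down = deg_down),
                                 tf_targets = target_set,
                                 expressed_min_tpm = cfg$expressed_min_tpm)
    kept <- tab$region
    dar_clusters <- NULL
    if (length(kept) >= cfg$k_dar) {
      wt <- design[design$genotype == "WT", ]
      rcpm <- cpmMatrix(region_counts, dar$factors)
      wt_means <- function(m) vapply(
        split(wt$sample_id, wt$condition)[c("HRFR", "LRFR_1h", "LRFR_25h")],
        function(sm) rowMeans(m[, sm, drop = FALSE]), numeric(nrow(m)))
      za <- rowZscore(wt_means(rcpm)[kept, , drop = FALSE])
      gene_of <- tab$gene_id[match(kept, tab$region)]
      zg <- rowZscore(wt_means(tpm)[gene_of, , drop = FALSE])
      zz <- cbind(za, zg)
      rownames(zz) <- kept
      dar_clusters <- hclusterRows(zz, cfg$k_dar)
      tab$cluster <- unname(dar_clusters[tab$region])
    }
    ## DARs directly bound: TF peak summit inside the region
    tfp <- simTfPeaks(sim)
    pts <- GRanges(seqnames(tfp), IRanges(peakReferencePoint(tfp), width = 1L))
    tab$dar_tf_bound <- IRanges::overlapsAny(dar_ranges[tab$region], pts,
                                             ignore.strand = TRUE)
    list(table = tab, clusters = dar_clusters)
  })

  report <- list(
    package = "chromShade",
    version = as.character(utils::packageVersion("chromShade")),
    seed = as.integer(seed),
    n_peaks_per_replicate = vapply(simPeaks(sim), length, 1L),
    n_consensus_raw = n_cons_raw,
    n_consensus = length(cons),
    pct_promoter_proximal = pct_promoter,
    n_tf_peaks = length(simTfPeaks(sim)),
    fraction_closed = access$fraction_closed,
    n_target_genes = length(target_set),
    n_deg_wt_1h = lengths(calls$wt_1h[c("up", "down")]),
    n_deg_wt_25h = lengths(calls$wt_25h[c("up", "down")]),
    n_deg_union = length(deg_union),
    n_deg_genotype_1h = lengths(calls$genotype_1h[c("up", "down")]),
    n_direct_targets = lengths(direct),
    n_dar_1h = length(dar_1h),
    n_dar_25h = length(dar_25h),
    n_dar_union = length(dar_union),
    n_dar_expressed = if (is.null(integ)) 0L else nrow(integ$table),
    n_dar_genes = if (is.null(integ)) 0L else
      length(unique(integ$table$gene_id)),
    n_dar_tf_bound = if (is.null(integ)) 0L else sum(integ$table$dar_tf_bound),
    deg_cluster_sizes = if (is.null(deg_clusters)) integer(0) else
      as.integer(table(deg_clusters)),
    dar_cluster_sizes = if (is.null(integ) || is.null(integ$clusters))
      integer(0) else as.integer(table(integ$clusters)))
  cfg_json <- jsonlite::toJSON(lapply(unclass(cfg), unclass),
                               auto_unbox = TRUE, digits = NA)
  report$config_hash <- as.character(tools::md5sum(
    local({ f <- file.path(out_dir, "config.json")
            writeLines(cfg_json, f); f })))

  ## consistency invariants of the run report
  stopifnot(all(direct$direct_up %in% intersect(calls$genotype_1h$up,
                                                target_set)),
            report$n_dar_expressed <= report$n_dar_union,
            report$n_consensus <= report$n_consensus_raw)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(deg))
    if (is.data.frame(deg[[nm]]))
      utils::write.table(deg[[nm]], file.path(out_dir,
                                              paste0("deg_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("wt_1h", "wt_25h"))
    utils::write.table(dar[[nm]], file.path(out_dir,
                                            paste0("dar_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(integ))
    utils::write.table(integ$table, file.path(out_dir, "integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(report = report, sim = sim, consensus = cons,
                 accessibility = access, targets = targets,
                 direct = direct, deg = deg, deg_calls = calls,
                 deg_sets = list(up = deg_up, down = deg_down,
                                 union = deg_union),
                 deg_clusters = deg_clusters,
                 dar = dar, dar_calls = dar_calls,
                 dar_sets = list(d1h = dar_1h, d25h = dar_25h,
                                 union = dar_union),
                 dar_ranges = dar_ranges,
                 integration = integ,
                 tpm = tpm, cond_means = cond_means))
}

#' Hash of a pipeline run report
#'
#' MD5 digest of the serialised `report.json`, for determinism checks.
#'
#' @param out_dir A pipeline output directory.
#' @return Character MD5 hash.
#' @export
reportHash <- function(out_dir) {
  unname(tools::md5sum(file.path(out_dir, "report.json")))
}
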