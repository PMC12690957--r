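## Synthetic shade-response experiment generator with planted ground truth.
##
## The generator emulates the statistical structure of a seedling
## shade-response multi-omics experiment: three biological replicates, two
## genotypes (wild type and a TF-loss mutant), three light conditions (high
## R:FR control, 1 h and 25 h of low R:FR), accessible chromatin regions
## concentrated 5' of TSSs, TF ChIP peaks mostly on open chromatin, and
## negative-binomial gene/region counts with planted expression and
## accessibility dynamics. Class memberships are fixed by deterministic
## rounding (half-up), not Bernoulli draws, so structural truth assertions
## are exact.

roundHalfUp <- function(x) floor(x + 0.5)

#' Simulation configuration
#'
#' Builds and validates the configuration list for
#' [simulateShadeExperiment()]. Defaults reflect the study conditions the
#' generator emulates: ~90% of accessible regions promoter-proximal (within
#' 2 kb 5' of a TSS), ~90% of TF peaks on open chromatin, three replicates,
#' NB2 counts with dispersion 0.1 and planted |log2 fold change| 1.5.
#'
#' @param n_chroms Number of nuclear chromosomes.
#' @param chrom_length Length of each nuclear chromosome (bp).
#' @param n_genes Number of genes.
#' @param n_regions Number of true accessible chromatin regions.
#' @param frac_promoter_proximal Fraction of regions whose midpoint lies
#'   within 2 kb 5' of a TSS (strand-aware); count fixed by half-up rounding.
#' @param n_tf_peaks Number of TF ChIP peaks.
#' @param frac_tf_peaks_open Fraction of TF peaks with summits inside true
#'   accessible regions.
#' @param gene_class_props Named proportions of non-null gene expression
#'   classes (`transient_up_tf_dep`, `slow_up_tf_dep`, `slow_up_tf_indep`,
#'   `transient_down`); the remainder is null.
#' @param region_class_props Named proportions of non-null accessibility
#'   classes over regions (`A_late_up`, `B_transient_up_tf_dep`,
#'   `C_variable`, `D_up_access_down_expr`); the remainder is null.
#' @param base_mean_range Log-uniform range of per-feature baseline mean
#'   counts.
#' @param lfc_effect Planted |log2 fold change| of all non-null dynamics.
#' @param dispersion NB2 dispersion phi (Var = mu + phi mu^2).
#' @param jitter_sd Replicate peak boundary jitter SD (bp).
#' @param frac_private_false_peaks Replicate-private false peaks per
#'   replicate, as a fraction of `n_regions` (count fixed by floor).
#' @param libsize_range Log-uniform range of per-sample library size factors.
#' @param gene_length_range Uniform range of gene body lengths (bp).
#' @param region_width_range Uniform range of accessible region widths (bp).
#' @param n_blacklist_promoter,n_blacklist_distal Number of null
#'   promoter-proximal / distal regions overlapped by blacklist decoys.
#' @param n_blacklist_decoy Extra blacklist intervals in empty genomic space.
#' @param replicates Biological replicates per genotype x condition.
#' @param organelle_chroms Named integer vector of organellar chromosome
#'   lengths (decoy chromosomes whose peaks must be filtered out).
#' @param organelle_peaks Named integer vector: decoy peaks per organellar
#'   chromosome (present in every replicate, so they survive consensus and
#'   exercise the organelle filter).
#' @return A validated configuration list of class `shadeSimConfig`.
#' @export
shadeSimConfig <- function(n_chroms = 3L,
                           chrom_length = 2e6,
                           n_genes = 1000L,
                           n_regions = 1200L,
                           frac_promoter_proximal = 0.9,
                           n_tf_peaks = 300L,
                           frac_tf_peaks_open = 0.9,
                           gene_class_props = c(transient_up_tf_dep = 0.05,
                                                slow_up_tf_dep = 0.05,
                                                slow_up_tf_indep = 0.03,
                                                transient_down = 0.02),
                           region_class_props = c(A_late_up = 0.02,
                                                  B_transient_up_tf_dep = 0.02,
                                                  C_variable = 0.01,
                                                  D_up_access_down_expr = 0.01),
                           base_mean_range = c(20, 2000),
                           lfc_effect = 1.5,
                           dispersion = 0.1,
                           jitter_sd = 25,
                           frac_private_false_peaks = 0.1,
                           libsize_range = c(0.5, 2),
                           gene_length_range = c(500, 1500),
                           region_width_range = c(250, 500),
                           n_blacklist_promoter = 9L,
                           n_blacklist_distal = 1L,
                           n_blacklist_decoy = 4L,
                           replicates = 3L,
                           organelle_chroms = c(ChrC = 154478L, ChrM = 367808L),
                           organelle_peaks = c(ChrC = 12L, ChrM = 8L)) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_regions = as.integer(n_regions),
              frac_promoter_proximal = frac_promoter_proximal,
              n_tf_peaks = as.integer(n_tf_peaks),
              frac_tf_peaks_open = frac_tf_peaks_open,
              gene_class_props = gene_class_props,
              region_class_props = region_class_props,
              base_mean_range = base_mean_range,
              lfc_effect = lfc_effect,
              dispersion = dispersion,
              jitter_sd = jitter_sd,
              frac_private_false_peaks = frac_private_false_peaks,
              libsize_range = libsize_range,
              gene_length_range = gene_length_range,
              region_width_range = region_width_range,
              n_blacklist_promoter = as.integer(n_blacklist_promoter),
              n_blacklist_distal = as.integer(n_blacklist_distal),
              n_blacklist_decoy = as.integer(n_blacklist_decoy),
              replicates = as.integer(replicates),
              organelle_chroms = organelle_chroms,
              organelle_peaks = organelle_peaks)
  fracs <- c(cfg$frac_promoter_proximal, cfg$frac_tf_peaks_open,
             cfg$frac_private_false_peaks)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (sum(cfg$gene_class_props) > 1 || any(cfg$gene_class_props < 0))
    stop("gene class proportions must be non-negative and sum to <= 1")
  if (sum(cfg$region_class_props) > 1 || any(cfg$region_class_props < 0))
    stop("region class proportions must be non-negative and sum to <= 1")
  if (any(c(cfg$n_chroms, cfg$n_genes, cfg$replicates) < 1))
    stop("n_chroms, n_genes and replicates must be positive")
  if (cfg$n_regions < 0 || cfg$n_tf_peaks < 0)
    stop("n_regions and n_tf_peaks must be non-negative")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  if (cfg$jitter_sd < 0) stop("jitter_sd must be non-negative")
  class(cfg) <- "shadeSimConfig"
  cfg
}

#' Sample design for the simulated experiment
#'
#' Full-factorial genotype x light-condition x replicate design with optional
#' red:far-red ratio metadata (control high R:FR ~1.5, low R:FR shade
#' treatment ~0.15).
#'
#' @param replicates Biological replicates per cell.
#' @param genotypes,conditions Factor levels.
#' @return A data.frame with columns `sample_id`, `genotype`, `condition`,
#'   `replicate`, `r_fr_ratio`.
#' @export
shadeDesign <- function(replicates = 3L,
                        genotypes = c("WT", "tf_mutant"),
                        conditions = c("HRFR", "LRFR_1h", "LRFR_25h")) {
  df <- expand.grid(replicate = seq_len(replicates),
                    condition = conditions, genotype = genotypes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("genotype", "condition", "replicate")]
  df$sample_id <- sprintf("%s_%s_rep%d", df$genotype, df$condition,
                          df$replicate)
  df$r_fr_ratio <- ifelse(df$condition == "HRFR", 1.5, 0.15)
  rownames(df) <- df$sample_id
  df[, c("sample_id", "genotype", "condition", "replicate", "r_fr_ratio")]
}

## Gene placement: chromosomes are divided into equal slots, one gene per
## slot, with a fixed margin on both sides wide enough to hold a 2 kb
## promoter window plus region widths and jitter. This guarantees
## non-overlapping gene bodies and well-separated regulatory regions.
.geneMargin <- 2200L

#' Simulate gene annotation, accessible-region truth and blacklist
#'
#' Places non-overlapping genes with random strands, plants accessible
#' chromatin regions (a half-up-rounded fraction with midpoints within 2 kb
#' 5' of a TSS, the rest centred on gene bodies), assigns expression and
#' accessibility truth classes with coupled gene/region dynamics, and builds
#' a blacklist whose decoys overlap a known subset of null regions.
#'
#' Deterministic given the RNG state; [simulateShadeExperiment()] seeds it.
#'
#' @param cfg A [shadeSimConfig()] list.
#' @return A list with elements `genes` (`GRanges`), `regions` (`GRanges`
#'   with truth columns `region_id`, `gene_id`, `class`,
#'   `promoter_proximal`, `blacklisted`), `blacklist` ([Blacklist-class]),
#'   and `gene_class` (named character vector).
#' @export
simulateAnnotation <- function(cfg) {
  stopifnot(inherits(cfg, "shadeSimConfig"))
  chroms <- paste0("Chr", seq_len(cfg$n_chroms))
  per_chrom <- rep(cfg$n_genes %/% cfg$n_chroms, cfg$n_chroms)
  extra <- cfg$n_genes %% cfg$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  max_len <- max(cfg$gene_length_range)
  slot_len <- floor(cfg$chrom_length / pmax(per_chrom, 1L))
  if (any(per_chrom > 0 & slot_len < max_len + 2L * .geneMargin))
    stop("infeasible gene placement: too many genes for the chromosome length")

  chrom_v <- rep(chroms, per_chrom)
  slot_idx <- unlist(lapply(per_chrom, seq_len))
  slot_start <- (slot_idx - 1L) * rep(slot_len, per_chrom)
  glen <- floor(stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                             cfg$gene_length_range[2] + 1))
  room <- rep(slot_len, per_chrom) - glen - 2L * .geneMargin
  gstart <- slot_start + .geneMargin + floor(stats::runif(cfg$n_genes) * (room + 1))
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- GRanges(chrom_v, IRanges(gstart + 1L, gstart + glen),
                   strand = gstrand)
  genes$gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  names(genes) <- genes$gene_id
  seqlengths(genes) <- stats::setNames(
    c(rep(cfg$chrom_length, cfg$n_chroms), cfg$organelle_chroms),
    c(chroms, names(cfg$organelle_chroms)))[seqlevels(genes)]
  tss <- tssPosition(genes)
  upstream_sign <- ifelse(as.character(strand(genes)) == "+", -1L, 1L)

  ## --- accessible regions -------------------------------------------------
  n_prom <- roundHalfUp(cfg$frac_promoter_proximal * cfg$n_regions)
  n_distal <- cfg$n_regions - n_prom
  if (n_distal > cfg$n_genes)
    stop("infeasible region placement: more distal regions than genes")

  if (n_prom <= cfg$n_genes) {
    host1 <- sample.int(cfg$n_genes, n_prom)
    host2 <- integer(0)
  } else {
    if (n_prom > 2L * cfg$n_genes)
      stop("infeasible region placement: more than two promoter regions per gene")
    host1 <- seq_len(cfg$n_genes)
    host2 <- sample.int(cfg$n_genes, n_prom - cfg$n_genes)
  }
  singles <- setdiff(host1, host2)

  wmin <- cfg$region_width_range[1]; wmax <- cfg$region_width_range[2]
  ## single-region promoters: midpoint 550-1750 bp 5' of the TSS;
  ## double-region promoters use narrower regions in two disjoint bands so
  ## that planted regions never touch even after replicate jitter.
  mk_prom <- function(gidx, off_lo, off_hi, w_lo, w_hi) {
    if (!length(gidx)) return(NULL)
    w <- floor(stats::runif(length(gidx), w_lo, w_hi + 1))
    off <- floor(stats::runif(length(gidx), off_lo, off_hi + 1))
    mid <- tss[gidx] + upstream_sign[gidx] * off
    data.frame(chrom = chrom_v[gidx], mid = mid, w = w,
               gene = genes$gene_id[gidx], promoter = TRUE)
  }
  parts <- list()
  parts$s <- mk_prom(singles, 550, 1750, wmin, min(wmax, 500))
  dbl <- intersect(host1, host2)
  parts$d1 <- mk_prom(dbl, 1425, 1800, wmin, min(wmax, 350))
  parts$d2 <- mk_prom(dbl, 575, 875, wmin, min(wmax, 350))
  if (n_distal > 0) {
    distal_gene <- sample.int(cfg$n_genes, n_distal)
    w <- floor(stats::runif(n_distal, wmin, wmax + 1))
    mid <- floor((start(genes)[distal_gene] + end(genes)[distal_gene]) / 2)
    parts$body <- data.frame(chrom = chrom_v[distal_gene], mid = mid, w = w,
                             gene = genes$gene_id[distal_gene],
                             promoter = FALSE)
  }
  tab <- do.call(rbind, parts)
  if (is.null(tab))
    tab <- data.frame(chrom = character(0), mid = integer(0), w = integer(0),
                      gene = character(0), promoter = logical(0))
  regions <- GRanges(tab$chrom,
                     IRanges(tab$mid - tab$w %/% 2L,
                             width = tab$w))
  regions$gene_id <- tab$gene
  regions$promoter_proximal <- tab$promoter
  ord <- GenomicRanges::order(regions)
  regions <- regions[ord]
  regions$region_id <- sprintf("region_%04d", seq_along(regions))
  names(regions) <- regions$region_id
  seqlevels(regions) <- seqlevels(genes)
  seqlengths(regions) <- seqlengths(genes)
  if (length(regions) > 1 && !all(GenomicRanges::isDisjoint(regions)))
    stop("internal error: planted regions overlap")

  ## --- blacklist ----------------------------------------------------------
  ## decoys overlap a known subset of (soon-to-be null) regions, split
  ## between promoter-proximal and distal so the surviving promoter fraction
  ## is preserved; extra decoys sit in empty space.
  n_bl_p <- min(cfg$n_blacklist_promoter, sum(regions$promoter_proximal))
  n_bl_d <- min(cfg$n_blacklist_distal, sum(!regions$promoter_proximal))
  resample <- function(x, n) x[sample.int(length(x), n)]
  bl_idx <- c(resample(which(regions$promoter_proximal), n_bl_p),
              resample(which(!regions$promoter_proximal), n_bl_d))
  regions$blacklisted <- seq_along(regions) %in% bl_idx
  bl_ranges <- GRanges()
  if (length(bl_idx)) {
    hit <- regions[bl_idx]
    bl_ranges <- GRanges(seqnames(hit),
                         IRanges(start(hit) - 50L, start(hit) + 100L))
  }
  if (cfg$n_blacklist_decoy > 0) {
    empty <- .rejectionPositions(cfg$n_blacklist_decoy, chroms,
                                 cfg$chrom_length, regions,
                                 min_dist = 1500L, min_self = 2000L)
    decoys <- GRanges(empty$chrom, IRanges(empty$pos, width = 500L))
    seqlevels(bl_ranges) <- seqlevels(regions)
    seqlevels(decoys) <- seqlevels(regions)
    bl_ranges <- c(bl_ranges, decoys)
  }
  bl <- blacklist(bl_ranges, organelles = names(cfg$organelle_chroms))

  ## --- truth classes ------------------------------------------------------
  n_gene_cls <- roundHalfUp(cfg$gene_class_props * cfg$n_genes)
  n_reg_cls <- roundHalfUp(cfg$region_class_props * cfg$n_regions)

  ## eligible hosts: genes with exactly one promoter-proximal region that is
  ## not blacklisted (unambiguous one-gene-one-region coupling)
  reg_ok <- regions$promoter_proximal & !regions$blacklisted
  gene_reg_count <- table(regions$gene_id[regions$promoter_proximal])
  single_hosts <- names(gene_reg_count)[gene_reg_count == 1L]
  single_hosts <- intersect(single_hosts, regions$gene_id[reg_ok])

  host_pool <- if (length(regions)) single_hosts else genes$gene_id
  need <- sum(n_gene_cls)
  if (need > length(host_pool))
    stop("not enough single-region genes to host the requested gene classes")
  class_genes <- host_pool[sample.int(length(host_pool), need)]
  gene_class <- stats::setNames(rep("null", cfg$n_genes), genes$gene_id)
  gene_class[class_genes] <- rep(names(n_gene_cls), n_gene_cls)

  pick_region_for <- function(gclass, n) {
    g <- names(gene_class)[gene_class == gclass]
    if (n > length(g))
      stop("region class demand exceeds available '", gclass, "' genes")
    g <- sample(g, n)
    idx <- which(reg_ok & regions$gene_id %in% g)
    idx[match(g, regions$gene_id[idx])]
  }
  region_class <- rep("null", length(regions))
  if (cfg$n_regions > 0 && sum(n_reg_cls) > 0) {
    region_class[pick_region_for("slow_up_tf_indep",
                                 n_reg_cls[["A_late_up"]])] <- "A_late_up"
    region_class[pick_region_for("transient_up_tf_dep",
                                 n_reg_cls[["B_transient_up_tf_dep"]])] <-
      "B_transient_up_tf_dep"
    region_class[pick_region_for("transient_down",
                                 n_reg_cls[["D_up_access_down_expr"]])] <-
      "D_up_access_down_expr"
    null_hosts <- names(gene_class)[gene_class == "null"]
    null_hosts <- intersect(null_hosts, single_hosts)
    cg <- sample(null_hosts, n_reg_cls[["C_variable"]])
    idx <- which(reg_ok & regions$gene_id %in% cg)
    region_class[idx[match(cg, regions$gene_id[idx])]] <- "C_variable"
  }
  regions$class <- region_class

  list(genes = genes, regions = regions, blacklist = bl,
       gene_class = gene_class)
}

## Rejection-sample positions on nuclear chromosomes at least `min_dist` bp
## from every interval in `avoid` and `min_self` bp from one another.
.rejectionPositions <- function(n, chroms, chrom_length, avoid,
                                min_dist = 1000L, min_self = 600L) {
  got_chrom <- character(0); got_pos <- integer(0)
  guard <- 0L
  while (length(got_pos) < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("rejection sampling failed to place positions")
    m <- max(4L * (n - length(got_pos)), 16L)
    cand_chrom <- sample(chroms, m, replace = TRUE)
    cand_pos <- floor(stats::runif(m, 2000, chrom_length - 2000))
    pts <- GRanges(cand_chrom, IRanges(cand_pos, width = 1L))
    if (length(avoid)) {
      suppressWarnings(seqlevels(pts) <- union(seqlevels(pts),
                                               seqlevels(avoid)))
      d <- GenomicRanges::distanceToNearest(pts, avoid, ignore.strand = TRUE)
      far <- rep(TRUE, m)
      far[queryHits(d)] <- mcols(d)$distance >= min_dist
    } else far <- rep(TRUE, m)
    for (i in which(far)) {
      if (length(got_pos) >= n) break
      same <- got_chrom == cand_chrom[i]
      if (!any(same) || all(abs(got_pos[same] - cand_pos[i]) >= min_self)) {
        got_chrom <- c(got_chrom, cand_chrom[i])
        got_pos <- c(got_pos, cand_pos[i])
      }
    }
  }
  list(chrom = got_chrom, pos = got_pos)
}

#' Simulate per-replicate ATAC peak calls
#'
#' Every true accessible region yields one peak per replicate with Gaussian
#' boundary jitter (rounded to integer bp, truncated so start < end). Each
#' replicate additionally receives `floor(frac_private_false_peaks *
#' n_regions)` private false peaks placed at least 1 kb from every true
#' region and far enough from each other that no private peak can find
#' support in another replicate. Organellar decoy peaks are present in every
#' replicate (they survive consensus and must be removed by the organelle
#' filter).
#'
#' @param ann Result of [simulateAnnotation()].
#' @param cfg A [shadeSimConfig()] list.
#' @return Named list of `GRanges`, one per replicate.
#' @export
simulateReplicatePeaks <- function(ann, cfg) {
  regions <- ann$regions
  chroms <- paste0("Chr", seq_len(cfg$n_chroms))
  n_private <- floor(cfg$frac_private_false_peaks * cfg$n_regions)
  total_private <- n_private * cfg$replicates
  priv <- if (total_private > 0)
    .rejectionPositions(total_private, chroms, cfg$chrom_length, regions,
                        min_dist = 1000L + max(cfg$region_width_range),
                        min_self = 2L * max(cfg$region_width_range))
  else list(chrom = character(0), pos = integer(0))

  org_base <- list()
  for (oc in names(cfg$organelle_peaks)) {
    k <- cfg$organelle_peaks[[oc]]
    if (k > 0) {
      len <- cfg$organelle_chroms[[oc]]
      pos <- floor(seq(from = len * 0.1, to = len * 0.9, length.out = k))
      org_base[[oc]] <- GRanges(oc, IRanges(pos, width = 300L))
    }
  }
  org_base <- lapply(org_base, function(g) {
    seqlevels(g) <- names(cfg$organelle_chroms); g
  })
  org_base <- if (length(org_base)) do.call(c, unname(org_base)) else GRanges()

  jitter_gr <- function(gr, sd) {
    if (sd == 0 || length(gr) == 0L) return(gr)
    s <- start(gr) + as.integer(round(stats::rnorm(length(gr), 0, sd)))
    e <- end(gr) + as.integer(round(stats::rnorm(length(gr), 0, sd)))
    e <- pmax(e, s)  # truncate: at least 1 bp wide
    GRanges(seqnames(gr), IRanges(s, e))
  }

  out <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    true_peaks <- jitter_gr(granges(regions), cfg$jitter_sd)
    idx <- if (n_private > 0) (r - 1L) * n_private + seq_len(n_private)
           else integer(0)
    priv_w <- if (length(idx))
      floor(stats::runif(length(idx), cfg$region_width_range[1],
                         cfg$region_width_range[2] + 1)) else integer(0)
    priv_peaks <- if (length(idx))
      GRanges(priv$chrom[idx], IRanges(priv$pos[idx] - priv_w %/% 2L,
                                       width = priv_w)) else GRanges()
    org_peaks <- jitter_gr(org_base, cfg$jitter_sd)
    sl <- stats::setNames(c(rep(cfg$chrom_length, cfg$n_chroms),
                            cfg$organelle_chroms),
                          c(chroms, names(cfg$organelle_chroms)))
    parts <- list(true_peaks, priv_peaks, org_peaks)
    parts <- lapply(parts, function(p) { seqlevels(p) <- names(sl); p })
    peaks <- do.call(c, parts)
    peaks <- GenomicRanges::sort(peaks)
    seqlengths(peaks) <- sl
    peaks$name <- sprintf("rep%d_peak_%05d", r, seq_along(peaks))
    peaks$score <- rep(100, length(peaks))
    peaks$signalValue <- rep(5, length(peaks))
    peaks$pValue <- rep(-1, length(peaks))
    peaks$qValue <- rep(-1, length(peaks))
    peaks$peakSummit <- width(peaks) %/% 2L
    names(peaks) <- peaks$name
    out[[r]] <- peaks
  }
  names(out) <- sprintf("rep%d", seq_len(cfg$replicates))
  out
}

#' Simulate TF ChIP peaks with open/closed truth
#'
#' A half-up-rounded fraction of peaks receive summits inside true accessible
#' regions ("open"); the rest are placed with summits at least 1 kb from any
#' accessible region ("closed"). Open peaks preferentially occupy the regions
#' of TF-dependent genes, mirroring a TF that binds the regulatory regions of
#' the genes whose shade response requires it. The true target-gene set is
#' recorded as every gene whose strand-aware window (3 kb 5' of the TSS to
#' 1 kb 3' of the TES) overlaps at least one peak.
#'
#' @param ann Result of [simulateAnnotation()].
#' @param cfg A [shadeSimConfig()] list.
#' @return List with `tf_peaks` (`GRanges` with truth columns `open`,
#'   `region_id`) and `target_genes` (character vector of gene ids).
#' @export
simulateTfPeaks <- function(ann, cfg) {
  regions <- ann$regions
  genes <- ann$genes
  n_open <- roundHalfUp(cfg$frac_tf_peaks_open * cfg$n_tf_peaks)
  n_closed <- cfg$n_tf_peaks - n_open

  tf_dep <- names(ann$gene_class)[ann$gene_class %in%
    c("transient_up_tf_dep", "slow_up_tf_dep", "transient_down")]
  ok <- which(!regions$blacklisted)
  pri <- ok[regions$gene_id[ok] %in% tf_dep]
  pri <- pri[!duplicated(regions$gene_id[pri])]
  rest <- setdiff(ok, pri)
  if (n_open > length(ok)) stop("not enough accessible regions for open TF peaks")
  open_idx <- if (n_open <= length(pri)) pri[seq_len(n_open)] else
    c(pri, sample(rest, n_open - length(pri)))

  host <- regions[open_idx]
  w4 <- width(host) %/% 4L
  summit <- start(host) + w4 +
    floor(stats::runif(length(host)) * (width(host) - 2L * w4))
  pw <- floor(stats::runif(length(host), 200, 401))
  open_gr <- GRanges(seqnames(host), IRanges(summit - pw %/% 2L, width = pw))
  open_gr$peakSummit <- as.integer(summit - start(open_gr))
  open_gr$open <- rep(TRUE, length(open_gr))
  open_gr$region_id <- host$region_id

  closed_gr <- GRanges()
  if (n_closed > 0) {
    chroms <- paste0("Chr", seq_len(cfg$n_chroms))
    pos <- .rejectionPositions(n_closed, chroms, cfg$chrom_length, regions,
                               min_dist = 1000L + max(cfg$region_width_range),
                               min_self = 600L)
    pw <- floor(stats::runif(n_closed, 200, 401))
    closed_gr <- GRanges(pos$chrom, IRanges(pos$pos - pw %/% 2L, width = pw))
    closed_gr$peakSummit <- as.integer(pos$pos - start(closed_gr))
    closed_gr$open <- FALSE
    closed_gr$region_id <- NA_character_
  }
  seqlevels(open_gr) <- seqlevels(regions)
  seqlevels(closed_gr) <- seqlevels(regions)
  tf <- c(open_gr, closed_gr)
  tf <- GenomicRanges::sort(tf)
  seqlengths(tf) <- seqlengths(regions)
  tf$name <- sprintf("tf_peak_%04d", seq_along(tf))
  n <- length(tf)
  tf$score <- rep(100, n); tf$signalValue <- rep(5, n)
  tf$pValue <- rep(-1, n); tf$qValue <- rep(-1, n)
  names(tf) <- tf$name

  ## geometric truth: genes whose 3 kb up / 1 kb down window catches a peak
  plus <- as.character(strand(genes)) == "+"
  win_start <- ifelse(plus, start(genes) - 3000L, start(genes) - 1000L)
  win_end <- ifelse(plus, end(genes) + 1000L, end(genes) + 3000L)
  wins <- GRanges(seqnames(genes), IRanges(pmax(1L, win_start), win_end))
  hits <- findOverlaps(wins, tf, ignore.strand = TRUE)
  target_genes <- sort(unique(genes$gene_id[queryHits(hits)]))

  list(tf_peaks = tf, target_genes = target_genes)
}

#' Draw negative-binomial (NB2) counts
#'
#' Samples counts with mean `mu` and variance `mu + dispersion * mu^2`;
#' `dispersion = 0` degenerates to Poisson.
#'
#' @param n Number of draws.
#' @param mu Positive mean (scalar or length-`n`).
#' @param dispersion Non-negative NB2 dispersion phi.
#' @return Integer vector of non-negative counts.
#' @examples
#' set.seed(1); mean(nbDraw(1e4, 5, 0))  # ~5
#' @export
nbDraw <- function(n, mu, dispersion) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (length(dispersion) != 1L || is.na(dispersion) || dispersion < 0)
    stop("dispersion must be a single non-negative number")
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Planted log2 expression/accessibility profile of a truth class
#'
#' Returns the planted log2 fold change relative to the baseline (HRFR) mean
#' for a feature of the given class in the given genotype and condition.
#' TF-dependent dynamics vanish in the `tf_mutant` genotype.
#'
#' @param class Truth class label (gene or region classes, or `"null"`).
#' @param genotype `"WT"` or `"tf_mutant"`.
#' @param condition `"HRFR"`, `"LRFR_1h"` or `"LRFR_25h"`.
#' @param lfc Planted effect magnitude (log2).
#' @return Numeric log2 fold change (vectorised over the first three
#'   arguments).
#' @export
plantedLog2Profile <- function(class, genotype, condition, lfc = 1.5) {
  n <- max(length(class), length(genotype), length(condition))
  class <- rep_len(class, n); genotype <- rep_len(genotype, n)
  condition <- rep_len(condition, n)
  wt <- genotype == "WT"
  at1 <- condition == "LRFR_1h"; at25 <- condition == "LRFR_25h"
  out <- numeric(n)
  out[class == "transient_up_tf_dep" & wt & at1] <- lfc
  out[class == "slow_up_tf_dep" & wt & at25] <- lfc
  out[class == "slow_up_tf_indep" & at25] <- lfc
  out[class == "transient_down" & wt & at1] <- -lfc
  out[class == "A_late_up" & at25] <- lfc
  out[class == "B_transient_up_tf_dep" & wt & at1] <- lfc
  out[class == "C_variable" & at25] <- -lfc
  out[class == "D_up_access_down_expr" & wt & at1] <- lfc
  out
}

#' Simulate gene and region count matrices
#'
#' Per-feature per-sample mean = baseline mean x 2^(planted class profile at
#' that genotype/condition) x library factor; counts are NB2 draws.
#'
#' @param ann Result of [simulateAnnotation()].
#' @param design A [shadeDesign()] data.frame with a `lib_factor` column
#'   (added here if absent).
#' @param cfg A [shadeSimConfig()] list.
#' @return List with integer matrices `gene_counts`, `region_counts`, the
#'   augmented `design`, and truth matrices `gene_mu`, `region_mu` of
#'   expected means (library factor excluded).
#' @export
simulateCounts <- function(ann, design, cfg) {
  if (is.null(design$lib_factor))
    design$lib_factor <- exp(stats::runif(nrow(design),
                                          log(cfg$libsize_range[1]),
                                          log(cfg$libsize_range[2])))
  draw <- function(classes, ids) {
    if (length(ids) == 0L) {
      empty <- matrix(0L, nrow = 0L, ncol = nrow(design),
                      dimnames = list(character(0), design$sample_id))
      return(list(counts = empty, mu = empty, base = numeric(0)))
    }
    base <- exp(stats::runif(length(ids), log(cfg$base_mean_range[1]),
                             log(cfg$base_mean_range[2])))
    prof <- vapply(seq_len(nrow(design)), function(j)
      plantedLog2Profile(classes, design$genotype[j], design$condition[j],
                         cfg$lfc_effect), numeric(length(ids)))
    mu <- base * 2^prof
    counts <- matrix(nbDraw(length(mu),
                            as.vector(t(t(mu) * design$lib_factor)),
                            cfg$dispersion),
                     nrow = length(ids),
                     dimnames = list(ids, design$sample_id))
    list(counts = counts, mu = `dimnames<-`(mu, list(ids, design$sample_id)),
         base = stats::setNames(base, ids))
  }
  g <- draw(ann$gene_class[ann$genes$gene_id], ann$genes$gene_id)
  r <- draw(ann$regions$class, ann$regions$region_id)
  list(gene_counts = g$counts, region_counts = r$counts, design = design,
       gene_mu = g$mu, region_mu = r$mu,
       gene_base_mean = g$base, region_base_mean = r$base)
}

#' Simulate a complete shade-response experiment
#'
#' Runs [simulateAnnotation()], [simulateReplicatePeaks()],
#' [simulateTfPeaks()] and [simulateCounts()] in a fixed order from a single
#' explicitly seeded RNG, so identical configuration and seed give identical
#' output.
#'
#' @param cfg A [shadeSimConfig()] list.
#' @param seed Integer RNG seed.
#' @return A [ShadeSim-class] object.
#' @examples
#' sim <- simulateShadeExperiment(shadeSimConfig(n_genes = 60, n_regions = 70,
#'   n_tf_peaks = 20, chrom_length = 4e5), seed = 1)
#' sim
#' @export
simulateShadeExperiment <- function(cfg = shadeSimConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  ann <- simulateAnnotation(cfg)
  peaks <- simulateReplicatePeaks(ann, cfg)
  tf <- simulateTfPeaks(ann, cfg)
  design <- shadeDesign(replicates = cfg$replicates)
  cm <- simulateCounts(ann, design, cfg)

  cd <- S4Vectors::DataFrame(cm$design, row.names = cm$design$sample_id)
  gse <- SummarizedExperiment(assays = list(counts = cm$gene_counts),
                              rowRanges = ann$genes, colData = cd)
  rse <- SummarizedExperiment(assays = list(counts = cm$region_counts),
                              rowRanges = ann$regions, colData = cd)
  tf$tf_peaks$target_gene <- ifelse(is.na(tf$tf_peaks$region_id), NA_character_,
    ann$regions$gene_id[match(tf$tf_peaks$region_id, ann$regions$region_id)])

  truth <- list(seed = as.integer(seed),
                gene_class = ann$gene_class,
                region_class = stats::setNames(ann$regions$class,
                                               ann$regions$region_id),
                region_gene = stats::setNames(ann$regions$gene_id,
                                              ann$regions$region_id),
                promoter_proximal = stats::setNames(ann$regions$promoter_proximal,
                                                    ann$regions$region_id),
                blacklisted = stats::setNames(ann$regions$blacklisted,
                                              ann$regions$region_id),
                tf_open = stats::setNames(tf$tf_peaks$open, tf$tf_peaks$name),
                target_genes = tf$target_genes,
                gene_mu = cm$gene_mu, region_mu = cm$region_mu,
                gene_base_mean = cm$gene_base_mean,
                region_base_mean = cm$region_base_mean,
                lib_factor = stats::setNames(cm$design$lib_factor,
                                             cm$design$sample_id))
  methods::new("ShadeSim", genes = ann$genes, regions = ann$regions,
               tfPeaks = tf$tf_peaks, peaks = peaks,
               geneCounts = gse, regionCounts = rse,
               blacklist = ann$blacklist, truth = truth,
               config = unclass(cfg))
}

#' Write the simulated fixture set to a directory
#'
#' Emits `genes.gff3`, `blacklist.bed`, `regions.bed` (the true accessible
#' regions that index the region count matrix), one
#' `peaks_rep<k>.narrowPeak` per replicate, `tf_peaks.narrowPeak`,
#' `counts_genes.tsv`, `counts_regions.tsv`, `design.tsv` and `truth.json`.
#'
#' @param sim A [ShadeSim-class] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeSimFixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGeneModels(simGenes(sim), file.path(dir, "genes.gff3"))
  bl <- simBlacklist(sim)
  blr <- blacklistRanges(bl)
  blr$name <- sprintf("blacklist_%03d", seq_along(blr))
  writeBed(blr, file.path(dir, "blacklist.bed"))
  reg <- simRegions(sim)
  reg$name <- reg$region_id
  writeBed(reg, file.path(dir, "regions.bed"))
  for (r in names(simPeaks(sim)))
    writeNarrowPeak(simPeaks(sim)[[r]],
                    file.path(dir, sprintf("peaks_%s.narrowPeak", r)))
  writeNarrowPeak(simTfPeaks(sim), file.path(dir, "tf_peaks.narrowPeak"))
  writeCountMatrix(assay(simGeneCounts(sim)),
                   file.path(dir, "counts_genes.tsv"))
  writeCountMatrix(assay(simRegionCounts(sim)),
                   file.path(dir, "counts_regions.tsv"))
  writeDesign(simDesign(sim), file.path(dir, "design.tsv"))
  tr <- simTruth(sim)
  tr$gene_mu <- NULL; tr$region_mu <- NULL  # large matrices stay in memory
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
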