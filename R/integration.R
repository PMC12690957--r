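## Z-scoring, hierarchical clustering and the set logic joining differential
## accessibility to differential expression.

#' Row z-scores
#'
#' Each row is centred by its mean and scaled by its sample standard
#' deviation (n - 1 denominator); rows with zero spread map to all zeros.
#'
#' @param x Numeric feature x column matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
rowZscore <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("row z-scores need at least two columns")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  z <- (x - mu) / sdv
  z[sdv == 0 | !is.finite(sdv), ] <- 0
  z
}

#' Hierarchical clustering of z-score rows
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`), cut to exactly `k` clusters. Cluster labels are renumbered
#' 1..k by decreasing size, ties broken by the lexicographically smallest
#' member feature id, so the labelling is independent of input row order.
#'
#' @param z Numeric matrix with feature rownames (e.g. from [rowZscore()]).
#' @param k Number of clusters (1 <= k <= nrow(z)).
#' @return Named integer vector of cluster labels (1..k), plus the `hclust`
#'   tree in attribute `"tree"`.
#' @export
hclusterRows <- function(z, k) {
  z <- as.matrix(z)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(z)) stop("k cannot exceed the number of features")
  if (is.null(rownames(z))) rownames(z) <- sprintf("f%05d", seq_len(nrow(z)))
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  size <- table(raw)
  first <- vapply(names(size),
                  function(cl) min(rownames(z)[raw == as.integer(cl)]), "")
  ord <- order(-as.integer(size), first)
  relabel <- stats::setNames(seq_len(k), names(size)[ord])
  out <- relabel[as.character(raw)]
  names(out) <- rownames(z)
  attr(out, "tree") <- tree
  out
}

#' Direct TF targets: DEGs intersected with bound genes
#'
#' @param deg_up,deg_down Character vectors of up-/down-regulated gene ids.
#' @param tf_targets Character vector of TF-bound gene ids.
#' @return List with sorted character vectors `direct_up`, `direct_down`.
#' @export
directTargets <- function(deg_up, deg_down, tf_targets) {
  list(direct_up = sort(intersect(deg_up, tf_targets)),
       direct_down = sort(intersect(deg_down, tf_targets)))
}

#' Per-cluster mean z-score trends
#'
#' @param z Numeric matrix with feature rownames.
#' @param clusters Named cluster labels (as from [hclusterRows()]).
#' @return List with `trend` (cluster x column matrix of mean z) and `n`
#'   (member counts).
#' @export
clusterTrend <- function(z, clusters) {
  z <- as.matrix(z)
  cl <- clusters[rownames(z)]
  labs <- sort(unique(cl))
  trend <- t(vapply(labs, function(l)
    colMeans(z[cl == l, , drop = FALSE]), numeric(ncol(z))))
  rownames(trend) <- labs
  list(trend = trend, n = stats::setNames(as.integer(table(cl)[as.character(labs)]),
                                          labs))
}

#' Join differentially accessible regions with expression evidence
#'
#' Annotates each DAR with its nearest gene, drops DARs whose gene is not
#' expressed (mean TPM below `expressed_min_tpm` in every wild-type
#' condition), and attaches DEG membership, TF-binding flags and cluster
#' labels.
#'
#' @param dars `GRanges` of differentially accessible regions (named).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param tpm Gene TPM matrix (genes x samples).
#' @param design Data.frame with `sample_id`, `genotype`, `condition`
#'   matching `tpm` columns.
#' @param deg_sets List with character vectors `up` and `down` of DEG ids.
#' @param tf_targets Character vector of TF-bound gene ids.
#' @param clusters Optional named cluster labels for the DARs.
#' @param expressed_min_tpm Expression floor (mean TPM in at least one
#'   wild-type condition). Default 1.
#' @param wt_genotype Genotype label treated as wild type.
#' @return A data.frame, one row per retained DAR: `region`, `gene_id`,
#'   `signed_distance`, `bin`, `mean_tpm_max`, `deg`, `deg_direction`,
#'   `tf_bound`, `cluster`.
#' @export
buildIntegrationTable <- function(dars, genes, tpm, design, deg_sets,
                                  tf_targets, clusters = NULL,
                                  expressed_min_tpm = 1,
                                  wt_genotype = "WT") {
  ann <- nearestTss(dars, genes)
  missing <- setdiff(ann$gene_id, rownames(tpm))
  if (length(missing))
    stop("gene absent from TPM matrix: ", missing[1])
  wt <- design[design$genotype == wt_genotype, ]
  cond_means <- vapply(split(wt$sample_id, wt$condition), function(sm)
    rowMeans(tpm[, sm, drop = FALSE]), numeric(nrow(tpm)))
  max_tpm <- apply(cond_means, 1L, max)[ann$gene_id]
  keep <- max_tpm >= expressed_min_tpm
  ann <- ann[keep, , drop = FALSE]
  deg_dir <- ifelse(ann$gene_id %in% deg_sets$up, "up",
                    ifelse(ann$gene_id %in% deg_sets$down, "down", "none"))
  data.frame(region = ann$peak,
             gene_id = ann$gene_id,
             signed_distance = ann$signed_distance,
             bin = ann$bin,
             mean_tpm_max = unname(max_tpm[keep]),
             deg = deg_dir != "none",
             deg_direction = deg_dir,
             tf_bound = ann$gene_id %in% tf_targets,
             cluster = if (is.null(clusters)) NA_integer_ else
               unname(clusters[ann$peak]))
}
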