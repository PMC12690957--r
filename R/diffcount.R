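## Normalisation, dispersion estimation and negative-binomial likelihood
## ratio testing of feature-by-sample count matrices.
##
## One NB2 likelihood-ratio test serves both gene expression and region
## accessibility; group means are fitted by one-dimensional Newton
## iterations on the log-mean with fixed per-feature dispersion and
## per-sample size-factor offsets, and the statistic is referred to a
## chi-squared distribution with one degree of freedom.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features (restricted to
#' features with a positive geometric mean across samples) of the ratio of
#' the sample's count to the feature's geometric mean. When no feature has
#' an all-positive row the method falls back to library-size ratios. Factors
#' are renormalised to geometric mean 1.
#'
#' @param counts Non-negative feature x sample matrix.
#' @return Positive numeric vector of per-sample factors (geometric mean 1).
#' @export
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  loggm <- rowMeans(log(counts))           # -Inf for rows with any zero
  use <- is.finite(loggm)
  if (any(use)) {
    f <- apply(counts[use, , drop = FALSE], 2L,
               function(cnt) stats::median(exp(log(cnt) - loggm[use])))
  } else {
    libs <- colSums(counts)
    if (any(libs == 0)) stop("sample with zero library size")
    f <- libs / mean(libs)
  }
  f / exp(mean(log(f)))
}

#' Counts per million
#'
#' `cpm_ij = count_ij / (factor_j x mean library size) x 1e6`, where the
#' library size is the column sum. Dividing by the mean library size (rather
#' than each sample's own) keeps samples on a common scale, since the size
#' factors already absorb the per-sample depth differences.
#'
#' @param counts Feature x sample count matrix.
#' @param factors Per-sample size factors (default all 1).
#' @return Numeric matrix of the same shape.
#' @export
cpmMatrix <- function(counts, factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample with zero library size")
  t(t(counts) / (factors * mean(libs))) * 1e6
}

#' Transcripts per million
#'
#' `tpm_ij = (count_ij / length_i) / sum_g(count_gj / length_g) x 1e6`;
#' columns sum to 1e6.
#'
#' @param counts Feature x sample count matrix.
#' @param lengths Positive feature lengths in bp.
#' @return Numeric matrix of the same shape.
#' @export
tpmMatrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) stop("sample with zero library size")
  t(t(rate) / denom) * 1e6
}

#' Method-of-moments dispersion estimation with shrinkage
#'
#' Per feature, on size-factor-normalised counts, the within-group residual
#' variance (pooled across design groups) and grand mean give the moment
#' estimate `phi_hat = max(0, (s2 - m) / m^2)`. The final tagwise value
#' shrinks half-way towards the across-feature median:
#' `phi = (1 - delta) phi_hat + delta phi_common` with `delta = 0.5`.
#'
#' @param counts Feature x sample count matrix.
#' @param groups Factor/vector of group labels per sample (at least one
#'   group must be replicated).
#' @param factors Per-sample size factors.
#' @param delta Shrinkage weight towards the common dispersion.
#' @return List with `tagwise` (per-feature phi), `raw` (unshrunk), and
#'   `common` (median phi).
#' @export
estimateDispersions <- function(counts, groups,
                                factors = rep(1, ncol(counts)),
                                delta = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (!any(table(groups) >= 2L)) stop("no replicated group in the design")
  x <- t(t(counts) / factors)
  gm <- rowMeans(x)
  ss <- 0; dfree <- 0
  for (g in levels(groups)) {
    j <- which(groups == g)
    if (length(j) < 2L) next
    mg <- rowMeans(x[, j, drop = FALSE])
    ss <- ss + rowSums((x[, j, drop = FALSE] - mg)^2)
    dfree <- dfree + (length(j) - 1L)
  }
  s2 <- ss / dfree
  raw <- ifelse(gm > 0, pmax(0, (s2 - gm) / gm^2), 0)
  common <- stats::median(raw)
  list(tagwise = (1 - delta) * raw + delta * common, raw = raw,
       common = common)
}

## Vectorised Newton fit of one NB mean per feature with per-sample offsets
## s_j: y_ij ~ NB(mu = s_j m_i, size = 1/phi_i). Returns list(mu, loglik,
## converged). Features whose row sum is zero get mu = 0 exactly.
.nbFitMean <- function(y, s, phi, tol = 1e-8, max_iter = 50L) {
  y <- as.matrix(y)
  nf <- nrow(y)
  rowsum_y <- rowSums(y)
  m <- rowsum_y / sum(s)              # Poisson/quasi start (exact MLE if phi=0)
  size <- ifelse(phi > 0, 1 / phi, Inf)
  converged <- rep(TRUE, nf)
  active <- which(rowsum_y > 0 & phi > 0)
  if (length(active)) {
    eta <- log(m[active])
    conv <- rep(FALSE, length(active))
    for (it in seq_len(max_iter)) {
      mu <- exp(eta) %o% s
      r <- size[active]
      frac <- mu / (mu + r)           # features x samples
      U <- rowSums(y[active, , drop = FALSE] -
                     (y[active, , drop = FALSE] + r) * frac)
      W <- rowSums((y[active, , drop = FALSE] + r) * r * frac / (mu + r))
      step <- U / W
      step <- pmax(pmin(step, 5), -5)  # damp wild steps far from optimum
      eta <- eta + step
      newly <- abs(step) < tol        # |delta eta| ~ |delta m| / m
      conv <- conv | newly
      if (all(abs(step) < tol)) break
    }
    m[active] <- exp(eta)
    converged[active] <- abs(step) < tol
  }
  mu <- pmax(m %o% s, 1e-12)
  ll_mat <- matrix(NA_real_, nrow = nf, ncol = ncol(y))
  pois <- !is.finite(size)
  if (any(pois))
    ll_mat[pois, ] <- stats::dpois(y[pois, , drop = FALSE],
                                   mu[pois, , drop = FALSE], log = TRUE)
  if (any(!pois))
    ll_mat[!pois, ] <- stats::dnbinom(y[!pois, , drop = FALSE],
                                      size = size[!pois],
                                      mu = mu[!pois, , drop = FALSE],
                                      log = TRUE)
  ll <- rowSums(ll_mat)
  ## exact zero-mean rows: likelihood of all-zero data at mu = 0 is 1
  zero <- rowsum_y == 0
  if (any(zero)) ll[zero] <- 0
  list(mu = m, loglik = ll, converged = converged)
}

#' Negative-binomial likelihood-ratio test between two groups
#'
#' For each feature, fits a null model (one common mean) and a full model
#' (one mean per group) to the counts of the two sample groups, with fixed
#' per-feature dispersion and per-sample size-factor offsets; means are
#' fitted by Newton iterations on the log mean (relative tolerance 1e-8,
#' at most 50 iterations). The statistic `2 (ll_full - ll_null)` is compared
#' to a chi-squared distribution with 1 df. The reported fold change is
#' `log2((mu_B + 0.5) / (mu_A + 0.5))` in normalised-count units; the
#' pseudocount keeps it finite for empty groups. Features whose fit does not
#' converge are flagged and given p = 1.
#'
#' @param counts Feature x sample count matrix.
#' @param group_A,group_B Character vectors of column names (each >= 2
#'   samples, disjoint).
#' @param factors Per-sample size factors named by sample (or in column
#'   order).
#' @param dispersions Per-feature phi (scalar recycled).
#' @param pseudocount Added to both group means for fold-change reporting.
#' @return A data.frame (one row per feature): `feature_id`, `base_mean`,
#'   `log2_fc` (B vs A), `dispersion`, `statistic`, `p_value`, `padj`,
#'   `converged`.
#' @export
nbTest <- function(counts, group_A, group_B,
                   factors = rep(1, ncol(counts)), dispersions = 0.1,
                   pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (length(intersect(group_A, group_B)))
    stop("contrast groups must be disjoint")
  if (length(group_A) < 2L || length(group_B) < 2L)
    stop("each contrast group needs at least two samples")
  if (!all(c(group_A, group_B) %in% colnames(counts)))
    stop("contrast samples missing from count matrix")
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  phi <- rep_len(dispersions, nrow(counts))
  if (any(phi < 0)) stop("dispersions must be non-negative")

  yA <- counts[, group_A, drop = FALSE]
  yB <- counts[, group_B, drop = FALSE]
  sA <- factors[group_A]; sB <- factors[group_B]

  fitA <- .nbFitMean(yA, sA, phi)
  fitB <- .nbFitMean(yB, sB, phi)
  fit0 <- .nbFitMean(cbind(yA, yB), c(sA, sB), phi)

  stat <- pmax(0, 2 * (fitA$loglik + fitB$loglik - fit0$loglik))
  converged <- fitA$converged & fitB$converged & fit0$converged
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p[!converged] <- 1
  if (any(!converged))
    warning(sum(!converged), " feature(s) did not converge; p set to 1")

  norm <- t(t(counts[, c(group_A, group_B), drop = FALSE]) /
              factors[c(group_A, group_B)])
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2_fc = log2((fitB$mu + pseudocount) /
                              (fitA$mu + pseudocount)),
             dispersion = phi,
             statistic = stat,
             p_value = p,
             padj = bhAdjust(p),
             converged = converged,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving.
#' A thin validating wrapper around the standard step-up implementation in
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partition test results into significant sets
#'
#' Strict inequalities on both criteria: up means `padj < alpha` and
#' `log2_fc > lfc_threshold`; down means `padj < alpha` and
#' `log2_fc < -lfc_threshold`. With `lfc_threshold = 0` any significant
#' nonzero fold change is called (the no-cutoff contrast).
#'
#' @param results A data.frame from [nbTest()].
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @return List with character vectors `up`, `down`, `ns` of feature ids.
#' @export
callSignificant <- function(results, alpha = 0.05, lfc_threshold = 0.6) {
  up <- results$padj < alpha & results$log2_fc > lfc_threshold
  down <- results$padj < alpha & results$log2_fc < -lfc_threshold
  list(up = results$feature_id[up],
       down = results$feature_id[down],
       ns = results$feature_id[!(up | down)])
}
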