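# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops over every peak/gene/p-value.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# enumerate the support predicate pairwise, then sweep-merge
bruteConsensus <- function(replicate_peaks, min_frac = 0.5) {
  merged <- lapply(replicate_peaks, function(gr)
    GenomicRanges::reduce(granges(gr), ignore.strand = TRUE))
  n <- length(merged)
  supported <- list()
  for (r in seq_len(n)) {
    p <- merged[[r]]
    for (i in seq_along(p)) {
      ok <- TRUE
      for (r2 in seq_len(n)) {
        if (r2 == r) next
        q <- merged[[r2]]
        best <- 0L
        for (j in seq_along(q)) {
          if (as.character(seqnames(p)[i]) != as.character(seqnames(q)[j]))
            next
          ov <- min(end(p)[i], end(q)[j]) - max(start(p)[i], start(q)[j]) + 1L
          best <- max(best, max(0L, ov))
        }
        if (best < min_frac * width(p)[i]) { ok <- FALSE; break }
      }
      if (ok) supported[[length(supported) + 1L]] <- p[i]
    }
  }
  if (!length(supported)) return(GRanges())
  all_sup <- suppressWarnings(do.call(c, supported))
  # manual sweep merge per chromosome (touching intervals merge)
  out <- GRanges()
  for (ch in sort(unique(as.character(seqnames(all_sup))))) {
    s <- sort(all_sup[seqnames(all_sup) == ch])
    cs <- start(s)[1]; ce <- end(s)[1]
    for (i in seq_along(s)[-1]) {
      if (start(s)[i] <= ce + 1L) ce <- max(ce, end(s)[i])
      else { out <- suppressWarnings(c(out, GRanges(ch, IRanges(cs, ce)))); cs <- start(s)[i]; ce <- end(s)[i] }
    }
    out <- suppressWarnings(c(out, GRanges(ch, IRanges(cs, ce))))
  }
  sort(out)
}

bruteNearestTss <- function(peaks, genes) {
  ref <- chromShade:::peakReferencePoint(peaks)
  out <- data.frame(gene_id = character(length(peaks)),
                    signed_distance = integer(length(peaks)))
  for (i in seq_along(peaks)) {
    best_d <- Inf; best_gene <- NA_character_; best_signed <- NA_integer_
    for (g in seq_along(genes)) {
      if (as.character(seqnames(peaks)[i]) != as.character(seqnames(genes)[g]))
        next
      tss <- if (as.character(strand(genes)[g]) == "+") start(genes)[g]
             else end(genes)[g]
      d <- abs(ref[i] - tss)
      gid <- genes$gene_id[g]
      if (d < best_d || (d == best_d && gid < best_gene)) {
        best_d <- d; best_gene <- gid
        best_signed <- if (as.character(strand(genes)[g]) == "+")
          ref[i] - tss else tss - ref[i]
      }
    }
    out$gene_id[i] <- best_gene
    out$signed_distance[i] <- best_signed
  }
  out
}

bruteCallTargets <- function(tf_peaks, genes, window_up = 3000,
                             window_down = 1000) {
  bound <- logical(length(genes))
  for (g in seq_along(genes)) {
    plus <- as.character(strand(genes)[g]) == "+"
    ws <- if (plus) start(genes)[g] - window_up else start(genes)[g] - window_down
    we <- if (plus) end(genes)[g] + window_down else end(genes)[g] + window_up
    for (i in seq_along(tf_peaks)) {
      if (as.character(seqnames(tf_peaks)[i]) != as.character(seqnames(genes)[g]))
        next
      if (min(end(tf_peaks)[i], we) - max(start(tf_peaks)[i], ws) + 1L >= 1L) {
        bound[g] <- TRUE; break
      }
    }
  }
  bound
}

# BH step-up from the definition: padj_i = min over k with p(k) >= p_i ...
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- m * ranked[i:m] / (i:m)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# grid-search maximiser of the NB log-likelihood for one group of counts
# with offsets s (mu_j = s_j * m), fixed dispersion phi
gridNBLoglik <- function(y, s, phi, n_grid = 1e5) {
  grid <- exp(seq(log(0.01), log(1e4), length.out = n_grid))
  size <- if (phi > 0) 1 / phi else Inf
  ll <- numeric(length(grid))
  for (j in seq_along(y)) {
    mu <- grid * s[j]
    ll <- ll + if (is.finite(size)) dnbinom(y[j], size = size, mu = mu, log = TRUE)
               else dpois(y[j], mu, log = TRUE)
  }
  max(ll)
}

randomPeakSet <- function(n_max = 10, coord_max = 1e4, chroms = c("Chr1", "Chr2")) {
  n <- sample.int(n_max, 1)
  s <- sample.int(coord_max - 200L, n, replace = TRUE)
  w <- sample(20:400, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w - 1L))
}
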