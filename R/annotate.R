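## Strand-aware peak-to-gene annotation.
##
## All three operations use a point representation of a peak (its summit if
## recorded, otherwise its midpoint) where a point rule applies; target
## calling uses the full peak interval against gene windows. Signed
## distances are strand-oriented: negative means 5' (upstream) of the TSS.

.distanceBins <- c("TSS", "promoter_0.1-2kb_5'", "upstream_2-3kb_5'",
                   "gene_body", "downstream", "distal")

#' Annotate peaks with their nearest TSS
#'
#' The reference point of each peak (summit, else midpoint) is matched to the
#' gene with the nearest TSS (ties broken by lexicographically smallest gene
#' id). The signed distance is `ref - tss` for `+` strand genes and
#' `tss - ref` for `-` strand genes, so negative distances are 5' of the TSS
#' regardless of strand. Distance bins: `TSS` (|d| <= 100),
#' `promoter_0.1-2kb_5'` (-2000 <= d < -100), `upstream_2-3kb_5'`
#' (-3000 <= d < -2000), `gene_body` (d > 100 and the point inside the gene
#' body), `downstream` (d > 100, past the gene body, within 1 kb of the
#' TES), else `distal`.
#'
#' @param peaks `GRanges` of peaks (optionally with `peakSummit`).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @return A data.frame with columns `peak`, `gene_id`, `signed_distance`,
#'   `bin`, one row per peak.
#' @export
nearestTss <- function(peaks, genes) {
  if (length(genes) == 0L) stop("empty gene list")
  if (length(peaks) == 0L)
    return(data.frame(peak = character(0), gene_id = character(0),
                      signed_distance = integer(0), bin = character(0)))
  ref <- peakReferencePoint(peaks)
  tss <- tssPosition(genes)
  gid <- genes$gene_id
  gchrom <- as.character(seqnames(genes))
  pchrom <- as.character(seqnames(peaks))
  plus <- as.character(strand(genes)) == "+"

  ## order genes by id within chromosome so the first minimal-distance match
  ## is the lexicographic tie-break winner
  out_gene <- character(length(peaks))
  out_dist <- integer(length(peaks))
  out_bin <- character(length(peaks))
  for (ch in unique(pchrom)) {
    gsel <- which(gchrom == ch)
    psel <- which(pchrom == ch)
    if (length(gsel) == 0L) {
      out_gene[psel] <- NA_character_
      out_dist[psel] <- NA_integer_
      out_bin[psel] <- "distal"
      next
    }
    gsel <- gsel[order(gid[gsel])]
    dmat <- abs(outer(ref[psel], tss[gsel], "-"))
    pick <- gsel[apply(dmat, 1L, which.min)]
    out_gene[psel] <- gid[pick]
    d <- ifelse(plus[pick], ref[psel] - tss[pick], tss[pick] - ref[psel])
    out_dist[psel] <- d
    inside <- ref[psel] >= start(genes)[pick] & ref[psel] <= end(genes)[pick]
    tes <- tesPosition(genes)[pick]
    past3p <- ifelse(plus[pick], ref[psel] - tes, tes - ref[psel])
    bin <- rep("distal", length(psel))
    bin[d > 100 & !inside & past3p > 0 & past3p <= 1000] <- "downstream"
    bin[d > 100 & inside] <- "gene_body"
    bin[d >= -3000 & d < -2000] <- "upstream_2-3kb_5'"
    bin[d >= -2000 & d < -100] <- "promoter_0.1-2kb_5'"
    bin[abs(d) <= 100] <- "TSS"
    out_bin[psel] <- bin
  }
  data.frame(peak = if (!is.null(names(peaks))) names(peaks) else
               sprintf("peak_%05d", seq_along(peaks)),
             gene_id = out_gene, signed_distance = out_dist, bin = out_bin)
}

#' Gene target windows for TF binding
#'
#' The window spans from `window_up` bp 5' of the TSS to `window_down` bp 3'
#' of the TES, strand-aware: `[start - up, end + down]` for `+` strand genes
#' and `[start - down, end + up]` for `-` strand genes.
#'
#' @param genes `GRanges` of gene models.
#' @param window_up,window_down Window extensions in bp (non-negative).
#' @return `GRanges` of windows, parallel to `genes`.
#' @export
targetWindows <- function(genes, window_up = 3000, window_down = 1000) {
  if (window_up < 0 || window_down < 0) stop("windows must be non-negative")
  plus <- as.character(strand(genes)) == "+"
  s <- ifelse(plus, start(genes) - window_up, start(genes) - window_down)
  e <- ifelse(plus, end(genes) + window_down, end(genes) + window_up)
  win <- GRanges(seqnames(genes), IRanges(pmax(1, s), e),
                 strand = strand(genes))
  win$gene_id <- genes$gene_id
  names(win) <- genes$gene_id
  win
}

#' Call TF target genes from ChIP peaks
#'
#' A gene is bound when at least one peak overlaps its target window by
#' >= 1 bp (full peak interval against the window); one peak may support
#' several genes.
#'
#' @param tf_peaks `GRanges` of TF ChIP peaks.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param window_up,window_down Window extensions in bp (default 3 kb
#'   upstream of the TSS, 1 kb downstream of the TES).
#' @return A data.frame with columns `gene_id`, `bound` (logical),
#'   `n_supporting_peaks`, and `supporting_peaks` (comma-separated names);
#'   one row per gene.
#' @export
callTargets <- function(tf_peaks, genes, window_up = 3000,
                        window_down = 1000) {
  win <- targetWindows(genes, window_up, window_down)
  hs <- harmoniseSeqlevels(win, tf_peaks)
  h <- findOverlaps(hs$x, hs$y, ignore.strand = TRUE)
  pk_names <- if (!is.null(names(tf_peaks))) names(tf_peaks) else
    sprintf("tf_peak_%05d", seq_along(tf_peaks))
  sup <- S4Vectors::splitAsList(pk_names[subjectHits(h)],
                                factor(queryHits(h),
                                       levels = seq_along(genes)))
  data.frame(gene_id = genes$gene_id,
             bound = lengths(sup) > 0L,
             n_supporting_peaks = lengths(sup),
             supporting_peaks = vapply(sup, paste, "", collapse = ","))
}

#' Classify TF binding sites as open or closed
#'
#' A peak is open when its reference point (summit, else midpoint) lies
#' inside a consensus accessible region; otherwise closed. The point rule
#' (rather than any-overlap) keeps the call independent of peak width.
#'
#' @param tf_peaks `GRanges` of TF ChIP peaks.
#' @param consensus A [ConsensusPeaks-class] object or `GRanges` of
#'   accessible regions.
#' @return A list with `calls` (data.frame: `peak`, `state`,
#'   `overlapping_region`) and `fraction_closed` (0 when there are no
#'   peaks).
#' @export
classifyAccessibility <- function(tf_peaks, consensus) {
  gr <- if (methods::is(consensus, "ConsensusPeaks"))
    consensusRanges(consensus) else consensus
  if (length(tf_peaks) == 0L)
    return(list(calls = data.frame(peak = character(0), state = character(0),
                                   overlapping_region = character(0)),
                fraction_closed = 0))
  pts <- GRanges(seqnames(tf_peaks),
                 IRanges(peakReferencePoint(tf_peaks), width = 1L))
  hs <- harmoniseSeqlevels(pts, gr)
  h <- findOverlaps(hs$x, hs$y, ignore.strand = TRUE)
  region_of <- rep(NA_character_, length(tf_peaks))
  rn <- if (!is.null(names(gr))) names(gr) else
    sprintf("region_%05d", seq_along(gr))
  region_of[queryHits(h)] <- rn[subjectHits(h)]
  state <- ifelse(is.na(region_of), "closed", "open")
  calls <- data.frame(
    peak = if (!is.null(names(tf_peaks))) names(tf_peaks) else
      sprintf("tf_peak_%05d", seq_along(tf_peaks)),
    state = state, overlapping_region = region_of)
  list(calls = calls, fraction_closed = mean(state == "closed"))
}
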