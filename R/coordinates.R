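## Interval arithmetic and gene-anatomy helpers.
##
## All in-memory coordinates follow the Bioconductor GRanges convention
## (1-based, closed). BED and narrowPeak files (0-based, half-open) are
## converted at the I/O boundary, GFF3 is already 1-based. Widths, overlaps
## and distances are therefore identical to their half-open formulations.

#' Overlap length between two interval sets, in bp
#'
#' Element-wise overlap length between parallel `GRanges` (both length 1 or
#' equal lengths). Intervals on different chromosomes overlap by 0 bp.
#'
#' @param a,b `GRanges` of equal length (or either of length 1, recycled).
#' @return Integer vector of non-negative overlap widths.
#' @examples
#' a <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(151, 250))
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  if (n == 0L) return(integer(0))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  out <- pmax(0L, ov)
  out[!same] <- 0L
  as.integer(out)
}

#' Merge intervals into a minimal disjoint cover
#'
#' Returns the minimal set of disjoint intervals covering the union of the
#' input, sorted by (chromosome, start). Touching intervals (adjacent in
#' half-open terms) are merged. Strand is ignored.
#'
#' @param x A `GRanges`.
#' @return A sorted, disjoint `GRanges`.
#' @export
mergeIntervals <- function(x) {
  if (length(x) == 0L) return(granges(x))
  GenomicRanges::reduce(granges(x), ignore.strand = TRUE)
}

#' Remove blacklisted and organellar intervals
#'
#' Drops every interval that overlaps a blacklist interval by at least 1 bp,
#' and every interval on an organellar chromosome, preserving the order of
#' the survivors. Removal at any overlap (rather than a fractional rule)
#' matches standard blacklist practice.
#'
#' @param x A `GRanges` of intervals (e.g. peaks).
#' @param bl A [Blacklist-class].
#' @return The subset of `x` that survives filtering.
#' @export
removeBlacklisted <- function(x, bl) {
  stopifnot(methods::is(bl, "Blacklist"))
  if (length(x) == 0L) return(x)
  drop <- as.character(seqnames(x)) %in% organelleChroms(bl)
  if (length(blacklistRanges(bl))) {
    h <- harmoniseSeqlevels(x, blacklistRanges(bl))
    drop <- drop | overlapsAny(h$x, h$y, ignore.strand = TRUE)
  }
  x[!drop]
}

## Put two GRanges on a shared seqlevel set so overlap queries between
## objects from different sources do not warn.
harmoniseSeqlevels <- function(x, y) {
  lv <- union(seqlevels(x), seqlevels(y))
  suppressWarnings({
    seqlevels(x) <- lv
    seqlevels(y) <- lv
  })
  list(x = x, y = y)
}

#' Transcription start / end sites of gene models
#'
#' The TSS is the strand-aware 5' end of the gene body (a start-codon proxy);
#' the TES is the 3' end. Both are single positions in the 1-based GRanges
#' convention.
#'
#' @param genes A `GRanges` of gene models with strand `+` or `-`.
#' @return Integer vector of positions, parallel to `genes`.
#' @export
tssPosition <- function(genes) {
  st <- as.character(strand(genes))
  if (any(st == "*"))
    stop("gene models must be stranded (+ or -)")
  ifelse(st == "+", start(genes), end(genes))
}

#' @rdname tssPosition
#' @export
tesPosition <- function(genes) {
  st <- as.character(strand(genes))
  if (any(st == "*"))
    stop("gene models must be stranded (+ or -)")
  ifelse(st == "+", end(genes), start(genes))
}

## Midpoint of an interval: floor((start0 + end0)/2) in half-open terms,
## expressed as the 1-based position start + floor(width/2).
intervalMidpoint <- function(x) {
  as.integer(pmin(start(x) + width(x) %/% 2L, end(x)))
}

## Reference point of a peak: the summit if a summit offset is recorded
## (narrowPeak column 10, 0-based offset from the peak start), otherwise the
## midpoint.
peakReferencePoint <- function(x) {
  mid <- intervalMidpoint(x)
  if (!is.null(x$peakSummit)) {
    off <- x$peakSummit
    use <- !is.na(off) & off >= 0L
    mid[use] <- as.integer(start(x)[use] + off[use])
  }
  mid
}
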