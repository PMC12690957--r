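#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList reduce findOverlaps pintersect
#'   granges strand seqnames start end width mcols mcols<- resize shift
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors DataFrame queryHits subjectHits Rle metadata metadata<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData rowRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Blacklist of artifact regions and organellar chromosomes
#'
#' Holds the genomic intervals with artifactual signal that are removed from
#' peak sets, together with the names of organellar chromosomes (by default
#' the plastid `ChrC` and mitochondrion `ChrM`) whose peaks are dropped
#' wholesale.
#'
#' @slot ranges A [GenomicRanges::GRanges] of blacklisted intervals.
#' @slot organelles Character vector of organellar chromosome names.
#' @seealso [blacklist()], [removeBlacklisted()]
#' @export
setClass("Blacklist",
  representation(ranges = "GRanges", organelles = "character"),
  prototype(organelles = c("ChrC", "ChrM"))
)

setValidity("Blacklist", function(object) {
  if (any(GenomicRanges::start(object@ranges) < 1))
    return("blacklist intervals must have positive coordinates")
  TRUE
})

#' Construct a Blacklist
#'
#' @param ranges `GRanges` of blacklisted intervals (may be empty).
#' @param organelles Character vector of organellar chromosome names whose
#'   peaks are removed regardless of coordinates.
#' @return A [Blacklist-class] object.
#' @examples
#' bl <- blacklist(GenomicRanges::GRanges("Chr1", IRanges::IRanges(100, 200)))
#' @export
blacklist <- function(ranges = GenomicRanges::GRanges(),
                      organelles = c("ChrC", "ChrM")) {
  ranges <- GenomicRanges::sort(ranges)
  methods::new("Blacklist", ranges = ranges, organelles = organelles)
}

setMethod("show", "Blacklist", function(object) {
  cat("Blacklist with", length(object@ranges), "intervals;",
      "organelle chromosomes:", paste(object@organelles, collapse = ", "), "\n")
})

#' @describeIn Blacklist-class the blacklisted intervals
#' @param x A `Blacklist`.
#' @export
blacklistRanges <- function(x) x@ranges

#' @describeIn Blacklist-class the organellar chromosome names
#' @export
organelleChroms <- function(x) x@organelles

#' Replicate-supported consensus accessible chromatin regions
#'
#' The result of [buildConsensus()]: disjoint regions supported, under a
#' fractional-overlap rule, by peaks in every biological replicate. The
#' underlying `GRanges` carries per-region provenance: the identifiers of the
#' supporting peaks from each replicate and the number of replicates
#' (`n_replicates_supporting`, equal to the total number of replicates by
#' construction).
#'
#' @slot ranges `GRanges` of consensus regions, sorted, with metadata columns
#'   `name`, `n_replicates_supporting`, and one `support.<rep>` column per
#'   replicate (CharacterList of contributing peak names).
#' @slot nReplicates Number of replicates the consensus was built from.
#' @slot minFrac The fractional-overlap threshold used.
#' @seealso [buildConsensus()], [filterConsensus()]
#' @export
setClass("ConsensusPeaks",
  representation(ranges = "GRanges", nReplicates = "integer",
                 minFrac = "numeric")
)

setValidity("ConsensusPeaks", function(object) {
  msg <- NULL
  if (length(object@ranges) > 1 &&
      !all(GenomicRanges::isDisjoint(object@ranges)))
    msg <- c(msg, "consensus regions must be disjoint")
  ns <- object@ranges$n_replicates_supporting
  if (!is.null(ns) && length(ns) && !all(ns == object@nReplicates))
    msg <- c(msg, "every consensus region must be supported in all replicates")
  if (object@minFrac <= 0 || object@minFrac > 1)
    msg <- c(msg, "minFrac must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConsensusPeaks", function(object) {
  cat("ConsensusPeaks:", length(object@ranges), "regions from",
      object@nReplicates, "replicates (min overlap fraction ",
      object@minFrac, ")\n", sep = " ")
  if (length(object@ranges)) methods::show(utils::head(object@ranges, 5))
})

#' @describeIn ConsensusPeaks-class the consensus regions as `GRanges`
#' @param x A `ConsensusPeaks` object.
#' @export
consensusRanges <- function(x) x@ranges

#' @describeIn ConsensusPeaks-class number of replicates used
#' @export
nReplicates <- function(x) x@nReplicates

#' @describeIn ConsensusPeaks-class number of consensus regions
#' @param object A `ConsensusPeaks` object.
#' @export
setMethod("length", "ConsensusPeaks", function(x) length(x@ranges))

#' A simulated shade-response experiment with planted ground truth
#'
#' Container returned by [simulateShadeExperiment()]. Bundles the synthetic
#' gene annotation, true accessible regions, per-replicate ATAC peak calls,
#' TF ChIP peaks, gene/region count matrices (as `SummarizedExperiment`s whose
#' `colData` is the sample design), the blacklist, and the ground-truth labels
#' used by recovery tests.
#'
#' @slot genes `GRanges` of gene models (`gene_id` in names and mcols).
#' @slot regions `GRanges` of true accessible regions with truth annotations
#'   (`region_id`, `class`, `gene_id`, `promoter_proximal`, `blacklisted`).
#' @slot tfPeaks `GRanges` of TF ChIP peaks with truth `open` labels.
#' @slot peaks A named list of `GRanges`, one per ATAC replicate.
#' @slot geneCounts `SummarizedExperiment` of gene counts (colData = design).
#' @slot regionCounts `SummarizedExperiment` of region counts.
#' @slot blacklist A [Blacklist-class].
#' @slot truth A list of ground-truth vectors and parameters (see
#'   [simulateShadeExperiment()]).
#' @slot config The validated configuration list used for simulation.
#' @export
setClass("ShadeSim",
  representation(genes = "GRanges", regions = "GRanges", tfPeaks = "GRanges",
                 peaks = "list", geneCounts = "RangedSummarizedExperiment",
                 regionCounts = "RangedSummarizedExperiment",
                 blacklist = "Blacklist", truth = "list", config = "list")
)

setValidity("ShadeSim", function(object) {
  msg <- NULL
  if (length(object@regions) &&
      is.null(object@regions$class))
    msg <- c(msg, "regions must carry a 'class' truth column")
  if (length(object@genes) &&
      !identical(nrow(object@geneCounts), length(object@genes)))
    msg <- c(msg, "gene count matrix rows must match gene models")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ShadeSim", function(object) {
  cat("ShadeSim:", length(object@genes), "genes,",
      length(object@regions), "accessible regions,",
      length(object@tfPeaks), "TF peaks,",
      length(object@peaks), "ATAC replicates,",
      ncol(object@geneCounts), "samples\n")
  cl <- table(object@regions$class)
  cat("  region classes:", paste(names(cl), cl, sep = "=", collapse = " "), "\n")
  cat("  gene classes:  ",
      paste(names(table(object@truth$gene_class)),
            table(object@truth$gene_class), sep = "=", collapse = " "), "\n")
})

#' @describeIn ShadeSim-class gene models
#' @param x A `ShadeSim` object.
#' @export
simGenes <- function(x) x@genes

#' @describeIn ShadeSim-class true accessible regions with truth labels
#' @export
simRegions <- function(x) x@regions

#' @describeIn ShadeSim-class TF ChIP peaks with truth labels
#' @export
simTfPeaks <- function(x) x@tfPeaks

#' @describeIn ShadeSim-class per-replicate ATAC peak calls
#' @export
simPeaks <- function(x) x@peaks

#' @describeIn ShadeSim-class gene-level `SummarizedExperiment`
#' @export
simGeneCounts <- function(x) x@geneCounts

#' @describeIn ShadeSim-class region-level `SummarizedExperiment`
#' @export
simRegionCounts <- function(x) x@regionCounts

#' @describeIn ShadeSim-class the blacklist
#' @export
simBlacklist <- function(x) x@blacklist

#' @describeIn ShadeSim-class ground-truth list
#' @export
simTruth <- function(x) x@truth

#' @describeIn ShadeSim-class sample design table (data.frame)
#' @export
simDesign <- function(x) as.data.frame(SummarizedExperiment::colData(x@geneCounts))
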