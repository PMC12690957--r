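## Quantitative PCR arithmetic: relative expression against two reference
## genes, ChIP percent-input, and accessible-chromatin enrichment normalised
## to open control regions. Technical replicates are averaged on the Ct
## (cycle) scale before any exponential transformation, matching common
## delta-delta-Ct practice; the amplification efficiency E (fold
## amplification per cycle) defaults to a perfect 2.

.checkE <- function(E) {
  if (length(E) != 1L || is.na(E) || E <= 1 || E > 2)
    stop("amplification efficiency E must lie in (1, 2]")
}

.avgCt <- function(ct) {
  if (any(ct <= 0)) stop("Ct values must be positive")
  mean(ct)
}

#' Relative expression normalised to two reference genes
#'
#' `E^(-Ct_target)` divided by the geometric mean of the two reference
#' quantities `E^(-Ct_ref)`. Technical replicates of any input are averaged
#' on the Ct scale first.
#'
#' @param ct_target Ct value(s) of the target gene (technical replicates).
#' @param ct_ref1,ct_ref2 Ct value(s) of the two reference genes.
#' @param E Amplification efficiency per cycle, in (1, 2].
#' @return Dimensionless relative expression.
#' @examples
#' relativeExpression(20, 18, 22)  # 1
#' @export
relativeExpression <- function(ct_target, ct_ref1, ct_ref2, E = 2) {
  .checkE(E)
  q <- E^(-.avgCt(ct_target))
  ref <- sqrt(E^(-.avgCt(ct_ref1)) * E^(-.avgCt(ct_ref2)))
  q / ref
}

#' Dilution-adjusted input Ct
#'
#' When only a fraction of chromatin is kept as input, its Ct is adjusted by
#' `log_E(1 / input_fraction)` cycles to the scale of the whole sample.
#'
#' @param ct_input Input Ct value(s).
#' @param input_fraction Fraction of chromatin reserved as input, in (0, 1].
#' @param E Amplification efficiency.
#' @return Adjusted Ct (scalar).
#' @export
adjustedInputCt <- function(ct_input, input_fraction = 0.1, E = 2) {
  .checkE(E)
  if (input_fraction <= 0 || input_fraction > 1)
    stop("input_fraction must lie in (0, 1]")
  .avgCt(ct_input) - log(1 / input_fraction, base = E)
}

#' ChIP-qPCR percent input
#'
#' `100 x E^(adjusted_input_Ct - Ct_IP)`.
#'
#' @param ct_ip IP Ct value(s).
#' @param ct_input Input Ct value(s).
#' @param input_fraction Fraction of chromatin reserved as input.
#' @param E Amplification efficiency.
#' @return Percent of input (0 to Inf).
#' @examples
#' percentInput(18, 20, input_fraction = 0.1)  # ~40
#' @export
percentInput <- function(ct_ip, ct_input, input_fraction = 0.1, E = 2) {
  .checkE(E)
  adj <- adjustedInputCt(ct_input, input_fraction, E)
  100 * E^(adj - .avgCt(ct_ip))
}

#' Enrichment of a region over its input
#'
#' `E^(adjusted_input_Ct - Ct_region)`: the building block of
#' accessible-chromatin qPCR quantification.
#'
#' @inheritParams percentInput
#' @param ct_region Ct of the purified accessible-chromatin fraction.
#' @return Dimensionless enrichment over input.
#' @export
enrichmentOverInput <- function(ct_region, ct_input, input_fraction = 0.1,
                                E = 2) {
  .checkE(E)
  E^(adjustedInputCt(ct_input, input_fraction, E) - .avgCt(ct_region))
}

#' Accessible-chromatin qPCR normalised to open control regions
#'
#' The region's enrichment over input divided by the geometric mean of the
#' enrichments of two constitutively open control regions (computed with the
#' same enrichment-over-input formula).
#'
#' @param ct_region,ct_input Ct values of the region in the purified
#'   accessible fraction and in the input.
#' @param ctrl_enrichments Numeric vector of two control-region enrichments
#'   (from [enrichmentOverInput()]); must be positive.
#' @param input_fraction Fraction of chromatin reserved as input.
#' @param E Amplification efficiency.
#' @return Dimensionless normalised accessibility.
#' @examples
#' copAccessibility(18, 20, ctrl_enrichments = c(0.4, 0.9))
#' @export
copAccessibility <- function(ct_region, ct_input, ctrl_enrichments,
                             input_fraction = 0.1, E = 2) {
  if (length(ctrl_enrichments) != 2L || any(ctrl_enrichments <= 0))
    stop("two positive control-region enrichments are required")
  enr <- enrichmentOverInput(ct_region, ct_input, input_fraction, E)
  enr / sqrt(prod(ctrl_enrichments))
}
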