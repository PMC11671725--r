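# Isotopocule algebra: delta notation, site preference, Rayleigh reduction
# shift, product ratios, background subtraction, soil-water correction.
# Internal unit conventions: deltas in per mil, atom fractions and product
# ratios dimensionless in [0, 1].

#' Delta value from isotope ratios
#'
#' Converts a sample/standard isotope-ratio pair to delta notation,
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000} per mil.
#'
#' @param rSample,rStandard positive isotope(ocule) ratios.
#' @return delta value in per mil.
#' @examples
#' deltaFromRatio(0.0037, R15_AIR_N2)   # ~6.39 permil
#' @export
deltaFromRatio <- function(rSample, rStandard) {
  if (any(rSample <= 0) || any(rStandard <= 0))
    stop("isotope ratios must be positive")
  (rSample / rStandard - 1) * 1000
}

#' Isotope ratio from a delta value
#'
#' Inverse of \code{\link{deltaFromRatio}}.
#'
#' @param delta delta value in per mil (must exceed -1000).
#' @param rStandard positive reference ratio.
#' @return isotope ratio.
#' @export
ratioFromDelta <- function(delta, rStandard) {
  if (any(delta <= -1000)) stop("delta must exceed -1000 permil")
  if (any(rStandard <= 0)) stop("isotope ratios must be positive")
  (delta / 1000 + 1) * rStandard
}

#' Bulk delta-15N and site preference from the alpha/beta positions
#'
#' The N2O molecule is asymmetric: alpha is the central N (adjacent to O),
#' beta the terminal N. Bulk is their average, site preference (SP) their
#' difference.
#'
#' @param alpha,beta per-mil delta-15N of the alpha and beta positions.
#' @return named numeric(2): \code{bulk}, \code{sp} (per mil).
#' @seealso \code{\link{alphaBetaFromBulkSp}}
#' @export
bulkSpFromAlphaBeta <- function(alpha, beta) {
  c(bulk = (alpha + beta) / 2, sp = alpha - beta)
}

#' @rdname bulkSpFromAlphaBeta
#' @param bulk,sp per-mil bulk delta-15N and site preference.
#' @return for the inverse: named numeric(2) \code{alpha}, \code{beta}.
#' @export
alphaBetaFromBulkSp <- function(bulk, sp) {
  c(alpha = bulk + sp / 2, beta = bulk - sp / 2)
}

#' Rayleigh closed-system reduction shift
#'
#' Isotopic signature of residual N2O after partial reduction to N2 under the
#' closed-system approximation: \eqn{\delta_r = \delta_0 + \epsilon \ln
#' r_{N2O}}, where r is the unreduced fraction. With the negative epsilon
#' values typical of N2O reduction the residual gas is enriched
#' (\eqn{\delta_r \ge \delta_0}).
#'
#' @param delta0 per-mil signature of the produced N2O before reduction.
#' @param epsilon per-mil net reduction isotope effect.
#' @param rN2O unreduced fraction (product ratio), in (0, 1].
#' @return per-mil signature of the residual N2O.
#' @examples
#' reductionShift(-1.90, -5, 0.4157)   # ~2.49 permil
#' @export
reductionShift <- function(delta0, epsilon, rN2O) {
  if (any(rN2O <= 0) || any(rN2O > 1))
    stop("rN2O must be in (0, 1]")
  delta0 + epsilon * log(rN2O)
}

#' Microscopic product ratios
#'
#' \code{microRatioRM} is the product ratio of the reducing (bacterial
#' denitrification) pool alone, N2O_bD / (N2O_bD + N2_bD), relevant when
#' reduction precedes mixing (RM scenario). \code{microRatioMR} is the ratio
#' over the whole emitted mixture, relevant when the mixed pool is reduced
#' (MR scenario).
#'
#' @param n2o,n2 non-negative fluxes (any common unit); not both zero.
#' @return fraction in [0, 1].
#' @export
microRatioRM <- function(n2o, n2) {
  if (any(n2o < 0) || any(n2 < 0)) stop("fluxes must be non-negative")
  if (any(n2o + n2 == 0)) stop("undefined ratio: both fluxes are zero")
  n2o / (n2o + n2)
}

#' @rdname microRatioRM
#' @export
microRatioMR <- function(n2o, n2) microRatioRM(n2o, n2)

#' Emitted-N2O signature by background subtraction
#'
#' Unmixes the measured headspace signature from the ambient-air background
#' by isotope mass balance:
#' \eqn{\delta_{emitted} = (C_{mix}\delta_{mix} - C_{air}\delta_{air}) /
#' (C_{mix} - C_{air})}.
#'
#' @param cMix,cAir N2O concentrations (ppm) of the headspace mixture and the
#'   pre-closure background; \code{cMix} must exceed \code{cAir}.
#' @param dMix,dAir corresponding per-mil delta values.
#' @return per-mil signature of the emitted N2O.
#' @export
emittedSignature <- function(cMix, dMix, cAir, dAir) {
  if (any(cAir < 0)) stop("concentrations must be non-negative")
  if (any(cMix <= cAir))
    stop("no emission: mixture concentration does not exceed background")
  (cMix * dMix - cAir * dAir) / (cMix - cAir)
}

#' Soil-water correction of delta-18O
#'
#' Re-expresses the delta-18O of N2O relative to soil water by subtracting
#' the soil-water delta-18O (both vs VSMOW), the convention under which the
#' source signatures are tabulated (assuming full O exchange with water).
#'
#' @param d18oN2O per-mil delta-18O of N2O vs VSMOW.
#' @param d18oH2O per-mil delta-18O of soil water vs VSMOW.
#' @return per-mil delta-18O of N2O vs soil water.
#' @export
waterCorrect <- function(d18oN2O, d18oH2O) d18oN2O - d18oH2O

#' Standard deviation from a reported literature range
#'
#' Literature source-signature ranges reported as mean +/- halfwidth are
#' interpreted as spanning mean +/- 2 SD, so the SD is half the halfwidth.
#'
#' @param rangeHalfwidth non-negative per-mil halfwidth.
#' @return per-mil standard deviation.
#' @export
sdFromRange <- function(rangeHalfwidth) {
  if (any(rangeHalfwidth < 0)) stop("range halfwidth must be non-negative")
  rangeHalfwidth / 2
}
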