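# Accessor generics and show methods for the core containers.

#' Source fractions of a result object
#'
#' @param object a \code{PartitionSolution}, \code{MonteCarloRun} or
#'   \code{PosteriorRun}.
#' @return For a \code{PartitionSolution}, the named fractions; for ensemble
#'   objects, the posterior/accepted-draw means.
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname fractions
#' @export
setMethod("fractions", "PartitionSolution", function(object) object@fractions)

#' @rdname fractions
#' @export
setMethod("fractions", "MonteCarloRun", function(object) {
  object@summary["mean", ]
})

#' @rdname fractions
#' @export
setMethod("fractions", "PosteriorRun", function(object) {
  object@summary["mean", N2O_PROCESSES]
})

#' Signature table of a SourceLibrary
#'
#' @param object a \code{SourceLibrary}.
#' @return data.frame of per-process SP and delta-18O means and SDs.
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))

#' @rdname signatures
#' @export
setMethod("signatures", "SourceLibrary", function(object) object@signatures)

#' Reduction isotope effects of a SourceLibrary
#'
#' @param object a \code{SourceLibrary}.
#' @return list with elements \code{epsSP} and \code{epsO}, each
#'   \code{c(mean, sd)} in per mil.
#' @export
setGeneric("reductionEffects", function(object) standardGeneric("reductionEffects"))

#' @rdname reductionEffects
#' @export
setMethod("reductionEffects", "SourceLibrary", function(object) {
  list(epsSP = object@epsSP, epsO = object@epsO)
})

#' Accepted draws / chain of an ensemble object
#'
#' @param object a \code{MonteCarloRun} or \code{PosteriorRun}.
#' @return matrix of draws (one row per accepted draw or kept iteration).
#' @export
setGeneric("draws", function(object) standardGeneric("draws"))

#' @rdname draws
#' @export
setMethod("draws", "MonteCarloRun", function(object) object@accepted)

#' @rdname draws
#' @export
setMethod("draws", "PosteriorRun", function(object) object@chain)

#' Acceptance statistics
#'
#' @param object a \code{MonteCarloRun} (count of feasible draws) or a
#'   \code{PosteriorRun} (Metropolis acceptance rate).
#' @return numeric scalar.
#' @export
setGeneric("acceptance", function(object) standardGeneric("acceptance"))

#' @rdname acceptance
#' @export
setMethod("acceptance", "MonteCarloRun", function(object) object@acceptanceCount)

#' @rdname acceptance
#' @export
setMethod("acceptance", "PosteriorRun", function(object) object@acceptanceRate)

#' Pool enrichment accessors
#'
#' @param object a \code{PoolEnrichment}.
#' @return numeric scalar: \code{poolAtomFraction} returns a_p, the 15N atom
#'   fraction of the emitting pool; \code{poolFraction} returns d, the
#'   fraction of the measured gas derived from that pool.
#' @export
setGeneric("poolAtomFraction", function(object) standardGeneric("poolAtomFraction"))

#' @rdname poolAtomFraction
#' @export
setMethod("poolAtomFraction", "PoolEnrichment", function(object) object@aP)

#' @rdname poolAtomFraction
#' @export
setGeneric("poolFraction", function(object) standardGeneric("poolFraction"))

#' @rdname poolAtomFraction
#' @export
setMethod("poolFraction", "PoolEnrichment", function(object) object@d)

# ---- show -------------------------------------------------------------------

.fmtPct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f%%"), 100 * x)

setMethod("show", "SourceLibrary", function(object) {
  cat("SourceLibrary: N2O source signatures (per mil; d18O vs soil water)\n")
  print(object@signatures, row.names = FALSE)
  cat(sprintf("Reduction effects: eps_SP = %.2f +/- %.2f, eps_O = %.2f +/- %.2f\n",
              object@epsSP[["mean"]], object@epsSP[["sd"]],
              object@epsO[["mean"]], object@epsO[["sd"]]))
})

setMethod("show", "EmittedMeasurement", function(object) {
  cat("EmittedMeasurement (emitted N2O)\n")
  cat(sprintf("  d15N-SP : %8.2f +/- %.2f permil\n", object@spMean, object@spSD))
  cat(sprintf("  d18O    : %8.2f +/- %.2f permil (vs soil water)\n",
              object@o18Mean, object@o18SD))
  cat(sprintf("  SPC     : %s +/- %s\n", .fmtPct(object@spcMean, 2),
              .fmtPct(object@spcSD, 2)))
  cat(sprintf("  R_N2O   : %s +/- %s\n", .fmtPct(object@rMean, 2),
              .fmtPct(object@rSD, 2)))
})

setMethod("show", "PartitionSolution", function(object) {
  cat("PartitionSolution:",
      paste(sprintf("%s = %s", N2O_PROCESSES, .fmtPct(object@fractions)),
            collapse = ", "), "\n")
})

setMethod("show", "MonteCarloRun", function(object) {
  cat(sprintf("MonteCarloRun (%s scenario): %d / %d draws accepted (%.2f%%)\n",
              object@scenario, object@acceptanceCount, object@nDraws,
              100 * object@acceptanceCount / object@nDraws))
  if (object@acceptanceCount > 0) {
    s <- object@summary
    for (p in colnames(s))
      cat(sprintf("  f_%-3s: %s +/- %s\n", p,
                  .fmtPct(s["mean", p]), .fmtPct(s["sd", p])))
  }
})

setMethod("show", "PosteriorRun", function(object) {
  cat(sprintf("PosteriorRun (%s scenario): %d kept states, acceptance %.1f%%\n",
              object@scenario, nrow(object@chain),
              100 * object@acceptanceRate))
  s <- object@summary
  for (p in colnames(s)) {
    lab <- if (p == "r") "r_N2O" else paste0("f_", p)
    cat(sprintf("  %-6s: %s +/- %s\n", lab,
                .fmtPct(s["mean", p]), .fmtPct(s["sd", p])))
  }
})

setMethod("show", "FluxSummary", function(object) {
  cat("FluxSummary (15N gas flux)\n")
  cat(sprintf("  N2O total       : %6.2f +/- %.2f ugN/kg/h\n",
              object@n2oTotal[["mean"]], object@n2oTotal[["sd"]]))
  cat(sprintf("  N2O denitrified : %6.2f +/- %.2f ugN/kg/h\n",
              object@n2oDenitrified[["mean"]], object@n2oDenitrified[["sd"]]))
  cat(sprintf("  N2 denitrified  : %6.2f +/- %.2f ugN/kg/h\n",
              object@n2Denitrified[["mean"]], object@n2Denitrified[["sd"]]))
  cat(sprintf("  SPC             : %s +/- %s\n",
              .fmtPct(object@spc[["mean"]], 2), .fmtPct(object@spc[["sd"]], 2)))
  cat(sprintf("  R_N2O           : %s +/- %s\n",
              .fmtPct(object@rMacro[["mean"]], 2),
              .fmtPct(object@rMacro[["sd"]], 2)))
  if (is.finite(object@aPN2O[["mean"]]))
    cat(sprintf("  a_p (N2O)       : %s,  a_p (N2): %s\n",
                .fmtPct(object@aPN2O[["mean"]], 2),
                .fmtPct(object@aPN2[["mean"]], 2)))
  if (nrow(object@dropped))
    cat(sprintf("  %d sample(s) below detection (see @dropped)\n",
                nrow(object@dropped)))
})

setMethod("show", "PoolEnrichment", function(object) {
  if (object@belowDetection) {
    cat("PoolEnrichment: below detection\n")
  } else {
    cat(sprintf("PoolEnrichment: a_p = %.4f, d = %.6f\n", object@aP, object@d))
  }
})
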