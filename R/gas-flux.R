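# 15N gas-flux (15NGF) stage: pool 15N enrichment and pool-derived gas
# fractions from N2 / N2O isotopologue ratios, concentration-to-flux
# conversion for the jar geometry, SPC and macroscopic product ratio.
#
# The two-pool model: headspace gas is a mixture of gas at the natural
# background atom fraction a_bgd (ambient gas plus emissions from unlabeled
# pools) and gas emitted from the 15N-labeled nitrate pool at atom fraction
# a_p, with isotopologues binomially paired within each pool. If d is the
# fraction of the headspace gas derived from the labeled pool, the excess
# mole fractions of the single- and double-heavy isotopologues over the
# background are
#   x_heavy1_xs = d * (2 a_p (1 - a_p) - 2 a_b (1 - a_b))
#   x_heavy2_xs = d * (a_p^2 - a_b^2)
# which invert in closed form through a quadratic in a_p.

# ambient N2 mole fraction, ppm; emitted N2 is negligible against it
C_N2_AMBIENT_PPM <- 780900

#' Default IRMS 1-sigma precisions for the isotopologue ratios
#'
#' Used as detection thresholds: a ratio excess below 3 sigma is flagged
#' below detection.
#'
#' @export
DEFAULT_IRMS_PRECISION <- c(r29 = 1.5e-6, r30 = 9.3e-6,
                            r45 = 3.1e-5, r46 = 8.2e-5)

.moleFractionsN2 <- function(r29, r30) {
  tot <- 1 + r29 + r30
  c(x29 = r29 / tot, x30 = r30 / tot)
}

.moleFractionsN2O <- function(r45, r46) {
  tot <- 1 + r45 + r46
  c(x45 = r45 / tot, x46 = r46 / tot)
}

#' Excess heavy-isotopologue mole fractions over the pre-closure background
#'
#' Converts the measured isotopologue ratios (to the light species: R29, R30
#' for N2; R45, R46 for N2O) of a headspace sample and of its same-replicate
#' background into mole fractions and returns the excess of the sample over
#' the background. Excesses may be negative within instrument noise; they
#' are flagged against 3-sigma detection thresholds, not clipped.
#'
#' @param sample,background one-row data.frame (or named list) with elements
#'   \code{r29}, \code{r30}, \code{r45}, \code{r46}.
#' @param precisions named 1-sigma ratio precisions (defaults
#'   \code{\link{DEFAULT_IRMS_PRECISION}}).
#' @param correct17O if TRUE, subtract the natural-abundance 17O contribution
#'   (17R = 3.799e-4) from R45 before conversion; default assumes R45 is
#'   already interference-corrected.
#' @return list with \code{n2} = c(x29_xs, x30_xs), \code{n2o} =
#'   c(x45_xs, x46_xs), and \code{belowDetection} = named logical(2).
#' @export
excessIsotopologueFractions <- function(sample, background,
                                        precisions = DEFAULT_IRMS_PRECISION,
                                        correct17O = FALSE) {
  if (is.null(background)) stop("background sample is required")
  getr <- function(x, nm) {
    v <- as.numeric(x[[nm]])
    if (length(v) != 1L || is.na(v)) stop("missing isotopologue ratio: ", nm)
    v
  }
  r <- lapply(c("r29", "r30", "r45", "r46"), function(nm)
    c(getr(sample, nm), getr(background, nm)))
  names(r) <- c("r29", "r30", "r45", "r46")
  if (correct17O) {
    r$r45 <- r$r45 - 3.799e-4
    r$r45[r$r45 < 0] <- 0
  }
  # a gas is below detection when neither of its heavy masses shows a
  # >= 3-sigma ratio excess
  below <- c(
    n2  = abs(r$r29[1] - r$r29[2]) < 3 * precisions[["r29"]] &&
          abs(r$r30[1] - r$r30[2]) < 3 * precisions[["r30"]],
    n2o = abs(r$r45[1] - r$r45[2]) < 3 * precisions[["r45"]] &&
          abs(r$r46[1] - r$r46[2]) < 3 * precisions[["r46"]])
  n2s <- .moleFractionsN2(r$r29[1], r$r30[1])
  n2b <- .moleFractionsN2(r$r29[2], r$r30[2])
  n2os <- .moleFractionsN2O(r$r45[1], r$r46[1])
  n2ob <- .moleFractionsN2O(r$r45[2], r$r46[2])
  list(n2 = stats::setNames(n2s - n2b, c("x29_xs", "x30_xs")),
       n2o = stats::setNames(n2os - n2ob, c("x45_xs", "x46_xs")),
       belowDetection = below)
}

#' Pool enrichment and pool-derived fraction from excess mole fractions
#'
#' Solves the binomial two-pool model for the unique (a_p, d) consistent
#' with the excess mole fractions of the single- and double-heavy
#' isotopologues. Eliminating d gives a quadratic in a_p,
#' \deqn{(2+K) a^2 - 2a + 2b - (2+K) b^2 = 0, \quad K = x_1/x_2,}
#' with b the background atom fraction; the physical root lies in (b, 1) and
#' d follows as \eqn{x_2 / (a^2 - b^2)}.
#'
#' @param xHeavy1Xs excess mole fraction of the single-heavy isotopologue
#'   (29N2 or 45N2O).
#' @param xHeavy2Xs excess mole fraction of the double-heavy isotopologue
#'   (30N2 or 46N2O).
#' @param aBgd background 15N atom fraction (default natural abundance).
#' @param dTol tolerance above 1 allowed for d before an inconsistency error.
#' @return A \code{\linkS4class{PoolEnrichment}}.
#' @examples
#' poolEnrichmentFromExcess(0.5, 0.25, 0)       # pure pool: a_p = 0.5, d = 1
#' @export
poolEnrichmentFromExcess <- function(xHeavy1Xs, xHeavy2Xs, aBgd = R15_AIR_N2,
                                     dTol = 1e-6) {
  if (!is.finite(xHeavy1Xs) || !is.finite(xHeavy2Xs))
    stop("excess mole fractions must be finite")
  if (xHeavy2Xs <= 0 || xHeavy1Xs <= 0)
    stop("below detection: non-positive excess mole fraction")
  K <- xHeavy1Xs / xHeavy2Xs
  b <- aBgd
  # the quadratic (2+K) a^2 - 2 a + (2b - (2+K) b^2) = 0 always has a = b as
  # one root; the physical root follows from the root sum 2 / (2+K)
  aP <- 2 / (2 + K) - b
  if (aP <= b || aP >= 1)
    stop("below detection: no enrichment root in (a_bgd, 1)")
  # 15N-atom-excess form of d; identical to x2 / (a^2 - b^2) on exact data,
  # but dominated by the better-determined single-heavy excess under noise
  d <- (xHeavy1Xs / 2 + xHeavy2Xs) / (aP - b)
  if (d < 0 || d > 1 + dTol)
    stop(sprintf("inconsistent excesses: implied pool fraction d = %.4g outside [0, 1]", d))
  new("PoolEnrichment", aP = aP, d = min(d, 1), belowDetection = FALSE)
}

#' Binomial two-pool forward model
#'
#' Expected excess heavy-isotopologue mole fractions for a pool of atom
#' fraction \code{aP} contributing fraction \code{d} of the headspace gas
#' over a background at \code{aBgd}. Exact inverse of
#' \code{\link{poolEnrichmentFromExcess}}.
#'
#' @param aP pool 15N atom fraction.
#' @param d fraction of the gas derived from the pool.
#' @param aBgd background atom fraction.
#' @return named numeric(2): \code{x_heavy1_xs}, \code{x_heavy2_xs}.
#' @export
twoPoolForward <- function(aP, d, aBgd = R15_AIR_N2) {
  c(x_heavy1_xs = d * (2 * aP * (1 - aP) - 2 * aBgd * (1 - aBgd)),
    x_heavy2_xs = d * (aP^2 - aBgd^2))
}

.molesHeadspace <- function(setup) {
  # ideal gas, 1 atm
  101325 * setup@headspaceVolume * 1e-3 / (8.31446 * (273.15 + setup@temperature))
}

# ppm of a gas with nAtomsN nitrogen atoms -> ugN per kg soil
.ppmToUgN <- function(ppm, setup, nAtomsN = 2) {
  ppm * 1e-6 * .molesHeadspace(setup) * nAtomsN * 14.0067e6 / setup@soilMass
}

.ugNToPpm <- function(ugN, setup, nAtomsN = 2) {
  ugN * setup@soilMass / (1e-6 * .molesHeadspace(setup) * nAtomsN * 14.0067e6)
}

#' Headspace concentration change to a flux
#'
#' Converts a ppm concentration increase over a time interval into a
#' nitrogen mass flux per kg of soil, using the ideal gas law at the setup
#' temperature and 1 atm.
#'
#' @param cT0,cT1 concentrations (ppm) at the start and end of the interval.
#' @param intervalH interval length in hours (> 0).
#' @param setup an \code{\linkS4class{IncubationSetup}}.
#' @param nAtomsN nitrogen atoms per molecule (2 for both N2O and N2).
#' @return flux in ugN kg-1 h-1.
#' @export
headspaceFlux <- function(cT0, cT1, intervalH, setup, nAtomsN = 2) {
  if (intervalH <= 0) stop("interval must be positive")
  if (setup@headspaceVolume <= 0) stop("headspace volume must be positive")
  .ppmToUgN(cT1 - cT0, setup, nAtomsN) / intervalH
}

#' Source partitioning coefficient from fluxes
#'
#' SPC = denitrified N2O / total emitted N2O, the fraction of emitted N2O
#' derived from the nitrate pool.
#'
#' @param n2oDenitrified,n2oTotal fluxes (same unit), with
#'   0 <= denitrified <= total and total > 0.
#' @return fraction in [0, 1].
#' @export
spcRatio <- function(n2oDenitrified, n2oTotal) {
  if (any(n2oTotal <= 0)) stop("total N2O flux must be positive")
  if (any(n2oDenitrified < -1e-9) || any(n2oDenitrified > n2oTotal + 1e-9))
    stop("denitrified N2O must lie between 0 and the total N2O flux")
  pmin(pmax(n2oDenitrified / n2oTotal, 0), 1)
}

#' Macroscopic product ratio from fluxes
#'
#' R_N2O = denitrified N2O / (denitrified N2O + denitrified N2). Fungal N2O
#' counts in the numerator but fungi produce no N2 (no N2O reductase), so R
#' is defined at the flux (macroscopic) level.
#'
#' @param n2oDenitrified,n2Denitrified non-negative fluxes, not both zero.
#' @return fraction in [0, 1].
#' @export
macroRatio <- function(n2oDenitrified, n2Denitrified) {
  if (any(n2oDenitrified < 0) || any(n2Denitrified < 0))
    stop("fluxes must be non-negative")
  if (any(n2oDenitrified + n2Denitrified == 0))
    stop("undefined ratio: both fluxes are zero")
  n2oDenitrified / (n2oDenitrified + n2Denitrified)
}

#' Validate a headspace time-series table
#'
#' @param samples data.frame with columns \code{replicate}, \code{time_h},
#'   \code{n2o_ppm}, \code{r29}, \code{r30}, \code{r45}, \code{r46}.
#' @return the table, invisibly, after checks.
#' @export
checkHeadspace <- function(samples) {
  need <- c("replicate", "time_h", "n2o_ppm", "r29", "r30", "r45", "r46")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("headspace table is missing columns: ", paste(miss, collapse = ", "))
  num <- samples[setdiff(need, "replicate")]
  if (any(!vapply(num, is.numeric, logical(1))))
    stop("headspace columns other than 'replicate' must be numeric")
  if (any(samples$time_h < 0)) stop("times must be non-negative")
  if (any(samples$n2o_ppm < 0) ||
      any(unlist(samples[c("r29", "r30", "r45", "r46")]) < 0))
    stop("concentrations and isotopologue ratios must be non-negative")
  invisible(samples)
}

# dilution bookkeeping: gas sampling replaces sampleVolume of headspace with
# ambient air, removing the fraction ls = Vs/Vhs of every accumulated excess
# quantity. Cumulative production up to time t_i is exactly the measured
# excess plus ls times the sum of excesses measured at earlier post-closure
# sampling events.
.dilutionCorrect <- function(measured, ls) {
  out <- measured
  if (length(measured) > 1)
    out <- measured + ls * c(0, cumsum(measured))[seq_along(measured)]
  out
}

.pipelineOneReplicate <- function(rep_df, setup, precisions, correct17O) {
  rep_df <- rep_df[order(rep_df$time_h), , drop = FALSE]
  if (nrow(rep_df) < 2) stop("each replicate needs at least 2 time points")
  bg <- rep_df[1, , drop = FALSE]
  post <- rep_df[-1, , drop = FALSE]
  ls <- setup@sampleVolume / setup@headspaceVolume
  aB <- setup@backgroundAtomFraction

  n <- nrow(post)
  pN2O <- pN2 <- numeric(n)       # pool-derived concentrations, ppm
  aPn2o <- aPn2 <- rep(NA_real_, n)
  okN2O <- okN2 <- logical(n)
  for (i in seq_len(n)) {
    xs <- excessIsotopologueFractions(post[i, ], bg, precisions, correct17O)
    if (!xs$belowDetection[["n2o"]]) {
      pe <- tryCatch(poolEnrichmentFromExcess(xs$n2o[["x45_xs"]],
                                              xs$n2o[["x46_xs"]], aB),
                     error = function(e) NULL)
      if (!is.null(pe)) {
        okN2O[i] <- TRUE
        aPn2o[i] <- pe@aP
        pN2O[i] <- pe@d * post$n2o_ppm[i]
      }
    }
    if (!xs$belowDetection[["n2"]]) {
      pe <- tryCatch(poolEnrichmentFromExcess(xs$n2[["x29_xs"]],
                                              xs$n2[["x30_xs"]], aB),
                     error = function(e) NULL)
      if (!is.null(pe)) {
        okN2[i] <- TRUE
        aPn2[i] <- pe@aP
        pN2[i] <- pe@d * C_N2_AMBIENT_PPM
      }
    }
  }
  last <- n
  if (!okN2O[last] || !okN2[last])
    return(list(ok = FALSE,
                dropped = data.frame(replicate = rep_df$replicate[1],
                                     time_h = post$time_h,
                                     below_detection_n2o = !okN2O,
                                     below_detection_n2 = !okN2)))

  eC <- post$n2o_ppm - bg$n2o_ppm
  eCcorr <- .dilutionCorrect(eC, ls)
  pN2Ocorr <- .dilutionCorrect(pN2O, ls)
  pN2corr <- .dilutionCorrect(pN2, ls)

  dt <- post$time_h[last] - bg$time_h
  fluxTotal <- .ppmToUgN(eCcorr[last], setup, 2) / dt
  fluxDenN2O <- .ppmToUgN(min(pN2Ocorr[last], eCcorr[last]), setup, 2) / dt
  fluxDenN2 <- .ppmToUgN(pN2corr[last], setup, 2) / dt
  list(ok = TRUE,
       row = data.frame(
         replicate = rep_df$replicate[1],
         n2o_total = fluxTotal,
         n2o_denitrified = fluxDenN2O,
         n2_denitrified = fluxDenN2,
         spc = spcRatio(fluxDenN2O, fluxTotal),
         r_macro = macroRatio(fluxDenN2O, fluxDenN2),
         a_p_n2o = aPn2o[last],
         a_p_n2 = aPn2[last]),
       dropped = if (any(!okN2O[-last] | !okN2[-last]))
         data.frame(replicate = rep_df$replicate[1],
                    time_h = post$time_h[-last][!okN2O[-last] | !okN2[-last]],
                    below_detection_n2o = !okN2O[-last][!okN2O[-last] | !okN2[-last]],
                    below_detection_n2 = !okN2[-last][!okN2O[-last] | !okN2[-last]])
       else data.frame())
}

#' Full 15N gas-flux pipeline
#'
#' Per replicate: takes the earliest time point as the pre-closure
#' background, computes excess isotopologue mole fractions at each later
#' time, inverts the two-pool model for (a_p, d) per gas, converts
#' dilution-corrected pool-derived and total excess concentrations to
#' fluxes, and forms SPC and the macroscopic product ratio. Ratios are
#' computed per replicate and then averaged across replicates; SDs are
#' across-replicate SDs. Samples whose ratio excesses fall below 3-sigma
#' detection thresholds are excluded and logged.
#'
#' @param samples headspace table, see \code{\link{checkHeadspace}}.
#' @param setup an \code{\linkS4class{IncubationSetup}}.
#' @param precisions IRMS 1-sigma ratio precisions.
#' @param correct17O see \code{\link{excessIsotopologueFractions}}.
#' @return A \code{\linkS4class{FluxSummary}}.
#' @export
gasfluxPipeline <- function(samples, setup = incubationSetup(),
                            precisions = DEFAULT_IRMS_PRECISION,
                            correct17O = FALSE) {
  checkHeadspace(samples)
  reps <- split(samples, samples$replicate)
  res <- lapply(reps, .pipelineOneReplicate, setup = setup,
                precisions = precisions, correct17O = correct17O)
  rows <- do.call(rbind, lapply(res, function(x) if (x$ok) x$row else NULL))
  dropped <- do.call(rbind, lapply(res, function(x)
    if (nrow(x$dropped)) x$dropped else NULL))
  if (is.null(dropped)) dropped <- data.frame()
  if (is.null(rows) || nrow(rows) == 0)
    stop("all replicates below detection; diagnostics: ",
         nrow(dropped), " sample(s) flagged, thresholds 3 x c(",
         paste(sprintf("%s=%.2g", names(precisions), precisions), collapse = ", "),
         ")")
  ms <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  fluxSummary(n2oTotal = ms(rows$n2o_total),
              n2oDenitrified = ms(rows$n2o_denitrified),
              n2Denitrified = ms(rows$n2_denitrified),
              spc = ms(rows$spc), rMacro = ms(rows$r_macro),
              aPN2O = ms(rows$a_p_n2o), aPN2 = ms(rows$a_p_n2),
              perReplicate = rows, dropped = dropped)
}
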