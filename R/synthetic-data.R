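# Forward simulator: generates synthetic measurements at both levels
# (summary emitted-N2O signatures; raw headspace isotopologue time series)
# from a known GroundTruth, so every inversion stage can be tested without
# external data.

#' Forward model: emitted-N2O measurement from a ground truth
#'
#' Computes the emitted-N2O signature implied by the true partition, product
#' ratio and library means: under RM the bD source is pre-shifted by
#' eps * ln(r) before mixing; under MR the mixture is shifted. SPC is
#' f_bD + f_fD. Optionally adds Gaussian instrument noise to the deltas and
#' ratio summaries.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param noise if TRUE, perturb the means with the truth's instrument SDs.
#' @param seed seed used when \code{noise} is TRUE.
#' @param spcSD,rSD SDs attached to (and, with \code{noise}, applied to) the
#'   SPC and R summaries; defaults are the across-replicate SDs of a
#'   4-replicate incubation of this design.
#' @return An \code{\linkS4class{EmittedMeasurement}}.
#' @export
forwardMeasurement <- function(truth, noise = FALSE, seed = 1,
                               spcSD = 0.0067, rSD = 0.0494) {
  stopifnot(validObject(truth))
  ld <- .asLibraryDraw(truth@library)
  f <- truth@partition@fractions
  pred <- .forwardPredict(f, truth@rN2O, ld, truth@scenario)
  sp <- pred[["sp"]]; o18 <- pred[["o18"]]; spc <- pred[["spc"]]
  rr <- macroRatio(spc * truth@n2oTotalFlux, truth@n2DenitrifiedFlux)
  if (noise) {
    set.seed(seed)
    sp <- sp + stats::rnorm(1, 0, truth@noise$d_sp)
    o18 <- o18 + stats::rnorm(1, 0, truth@noise$d_o18)
    spc <- min(max(spc + stats::rnorm(1, 0, spcSD), 0), 1)
    rr <- min(max(rr + stats::rnorm(1, 0, rSD), 1e-6), 1)
  }
  emittedMeasurement(spMean = sp, spSD = truth@noise$d_sp,
                     o18Mean = o18, o18SD = truth@noise$d_o18,
                     spcMean = spc, spcSD = spcSD,
                     rMean = rr, rSD = rSD)
}

#' Simulate a jar-incubation headspace time series
#'
#' Emulates a 15NGF incubation: four replicates sampled at 0, 3, 6 and 24 h.
#' Concentrations accumulate from the true fluxes (inverse of
#' \code{\link{headspaceFlux}}); each sampling event replaces
#' \code{sampleVolume} of headspace with ambient air, scaling all excess
#' quantities by (1 - Vs/Vhs). Isotopologue ratios follow the binomial
#' two-pool model: the labeled (nitrate-derived) fraction of headspace N2O
#' is SPC-weighted emitted gas over total, of N2 the denitrified flux over
#' ambient N2. Gaussian instrument noise (GC on concentration, IRMS on each
#' ratio) is added per sample.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}; set its noise entries to
#'   0 for an exact, invertible dataset.
#' @param setup an \code{\linkS4class{IncubationSetup}}.
#' @param seed integer seed.
#' @param times sampling times in hours (first is the pre-closure background).
#' @param nReplicates number of jars.
#' @param ambientN2OPpm ambient N2O concentration.
#' @return headspace data.frame (see \code{\link{checkHeadspace}}).
#' @export
simulateIncubation <- function(truth, setup = incubationSetup(), seed = 1,
                               times = c(0, 3, 6, 24), nReplicates = 4,
                               ambientN2OPpm = 0.33) {
  stopifnot(validObject(truth), validObject(setup))
  set.seed(seed)
  times <- sort(times)
  k <- 1 - setup@sampleVolume / setup@headspaceVolume
  aB <- setup@backgroundAtomFraction
  aP <- truth@poolAP
  spcTrue <- truth@partition@spc

  ratePpm <- .ugNToPpm(truth@n2oTotalFlux, setup, 2)       # ppm N2O per hour
  rateN2Ppm <- .ugNToPpm(truth@n2DenitrifiedFlux, setup, 2)
  prod <- function(t) pmax(0, t - truth@lagHours)

  x45b <- 2 * aB * (1 - aB); x46b <- aB^2
  x45p <- 2 * aP * (1 - aP); x46p <- aP^2

  out <- vector("list", nReplicates)
  for (rep_i in seq_len(nReplicates)) {
    nT <- length(times)
    eC <- pN2O <- pN2 <- numeric(nT)     # measured excesses, ppm
    for (j in seq_along(times)[-1]) {
      dProd <- prod(times[j]) - prod(times[j - 1])
      eC[j] <- k * eC[j - 1] + ratePpm * dProd
      pN2O[j] <- k * pN2O[j - 1] + spcTrue * ratePpm * dProd
      pN2[j] <- k * pN2[j - 1] + rateN2Ppm * dProd
    }
    cN2O <- ambientN2OPpm + eC
    dN2O <- pN2O / cN2O
    dN2 <- pN2 / C_N2_AMBIENT_PPM
    x45 <- x45b + dN2O * (x45p - x45b)
    x46 <- x46b + dN2O * (x46p - x46b)
    x29 <- x45b + dN2 * (x45p - x45b)    # same binomial fractions for N2
    x30 <- x46b + dN2 * (x46p - x46b)
    df <- data.frame(
      replicate = paste0("R", rep_i),
      time_h = times,
      n2o_ppm = pmax(0, cN2O + stats::rnorm(nT, 0, truth@noise$gc_ppm)),
      r29 = pmax(0, x29 / (1 - x29 - x30) + stats::rnorm(nT, 0, truth@noise$r29)),
      r30 = pmax(0, x30 / (1 - x29 - x30) + stats::rnorm(nT, 0, truth@noise$r30)),
      r45 = pmax(0, x45 / (1 - x45 - x46) + stats::rnorm(nT, 0, truth@noise$r45)),
      r46 = pmax(0, x46 / (1 - x45 - x46) + stats::rnorm(nT, 0, truth@noise$r46)))
    out[[rep_i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate-and-invert recovery experiment
#'
#' Repeatedly simulates an incubation plus a parallel natural-abundance
#' measurement from the same ground truth, runs the gas-flux pipeline and
#' the chosen partitioning method, and tabulates per-fraction bias and RMSE
#' of the recovered means against the generating partition.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param method "ls" (constrained Monte Carlo) or "bayes" (posterior
#'   sampler).
#' @param reps number of simulated experiments.
#' @param seed integer seed.
#' @param nDraws Monte Carlo draws per LS inversion.
#' @param nIter iterations per Bayesian inversion.
#' @param setup an \code{\linkS4class{IncubationSetup}}.
#' @param precisions IRMS detection thresholds passed to
#'   \code{\link{gasfluxPipeline}}; set to zeros for noise-free truths.
#' @return list with \code{estimates} (reps x 4 matrix of recovered means),
#'   \code{bias}, \code{rmse} (named numeric(4)) and \code{truth}.
#' @export
recoveryExperiment <- function(truth, method = c("ls", "bayes"), reps = 5,
                               seed = 1, nDraws = 20000, nIter = 20000,
                               setup = incubationSetup(),
                               precisions = DEFAULT_IRMS_PRECISION) {
  method <- match.arg(method)
  if (reps < 1) stop("reps must be at least 1")
  est <- matrix(NA_real_, nrow = reps, ncol = 4,
                dimnames = list(NULL, N2O_PROCESSES))
  for (i in seq_len(reps)) {
    sd_i <- seed + i
    hs <- simulateIncubation(truth, setup, seed = sd_i)
    fl <- gasfluxPipeline(hs, setup, precisions = precisions)
    em0 <- forwardMeasurement(truth, noise = TRUE, seed = sd_i + 10000)
    meas <- emittedMeasurement(
      spMean = em0@spMean, spSD = em0@spSD,
      o18Mean = em0@o18Mean, o18SD = em0@o18SD,
      spcMean = fl@spc[["mean"]], spcSD = max(fl@spc[["sd"]], 1e-4),
      rMean = fl@rMacro[["mean"]], rSD = max(fl@rMacro[["sd"]], 1e-4))
    if (method == "ls") {
      run <- monteCarloPartition(truth@library, meas, truth@scenario,
                                 nDraws = nDraws, seed = sd_i + 20000)
      est[i, ] <- run@summary["mean", ]
    } else {
      cfg <- bayesConfig(nIter = nIter, seed = sd_i + 20000,
                         scenario = truth@scenario)
      run <- samplePosterior(meas, truth@library, cfg)
      est[i, ] <- run@summary["mean", N2O_PROCESSES]
    }
  }
  fTrue <- truth@partition@fractions
  bias <- colMeans(est) - fTrue
  rmse <- sqrt(colMeans((est - matrix(fTrue, reps, 4, byrow = TRUE))^2))
  list(estimates = est, bias = bias, rmse = rmse, truth = fTrue)
}
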