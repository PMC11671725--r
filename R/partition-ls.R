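# Constrained Monte Carlo solution of the augmented linear systems that fuse
# the natural-abundance isotopocule mixing equations with the 15N gas-flux
# constraints.
#
# Row structure of the 4 x 5 augmented system (unknowns f_bD, f_fD, f_Ni,
# f_nD):
#   1: d18O of the four (effective) sources      | d18O of the sample
#   2: d15N-SP of the four (effective) sources   | SP of the sample
#   3: 1 1 0 0                                   | SPC
#   4: 1 1 1 1                                   | 1
# In the RM scenario (reduction before mixing) the Rayleigh shift
# eps * ln(r) applies to the bacterial-denitrification source only; in the
# MR scenario (mixing before reduction) the shift moves to the right-hand
# side of the two isotope rows, i.e. it applies to the whole mixture.

.asLibraryDraw <- function(library) {
  sig <- library@signatures
  list(sp = stats::setNames(sig$sp_mean, sig$process),
       o18 = stats::setNames(sig$o18_mean, sig$process),
       epsSP = library@epsSP[["mean"]],
       epsO = library@epsO[["mean"]])
}

#' Effective source signatures under a scenario
#'
#' In the RM scenario the bacterial-denitrification signature is shifted by
#' the Rayleigh term \code{eps * log(r)} in both isotope dimensions before
#' mixing; all other sources, and all sources under MR, are returned
#' unchanged (under MR the shift applies to the mixture and is handled on
#' the right-hand side of the system).
#'
#' @param libraryDraw list with \code{sp}, \code{o18} (named numeric(4) in
#'   bD, fD, Ni, nD order) and \code{epsSP}, \code{epsO} scalars; e.g. one
#'   Monte Carlo draw, or the library means.
#' @param scenario "RM" or "MR".
#' @param rDraw product ratio in (0, 1].
#' @return list with shifted \code{sp} and \code{o18} vectors.
#' @export
effectiveSources <- function(libraryDraw, scenario = c("RM", "MR"), rDraw) {
  scenario <- match.arg(scenario)
  if (rDraw <= 0 || rDraw > 1) stop("rDraw must be in (0, 1]")
  sp <- libraryDraw$sp
  o18 <- libraryDraw$o18
  if (scenario == "RM") {
    sp[["bD"]] <- reductionShift(sp[["bD"]], libraryDraw$epsSP, rDraw)
    o18[["bD"]] <- reductionShift(o18[["bD"]], libraryDraw$epsO, rDraw)
  }
  list(sp = sp, o18 = o18)
}

#' Build the augmented mixing system
#'
#' @param libraryDraw as in \code{\link{effectiveSources}}.
#' @param measurementDraw list with scalars \code{sp}, \code{o18},
#'   \code{spc}: the (drawn) emitted-N2O signature and SPC.
#' @param scenario "RM" or "MR".
#' @param rDraw product ratio in (0, 1].
#' @return 4 x 5 augmented matrix; columns bD, fD, Ni, nD, rhs.
#' @export
buildSystem <- function(libraryDraw, measurementDraw,
                        scenario = c("RM", "MR"), rDraw) {
  scenario <- match.arg(scenario)
  eff <- effectiveSources(libraryDraw, scenario, rDraw)
  rhsO18 <- measurementDraw$o18
  rhsSP <- measurementDraw$sp
  if (scenario == "MR") {
    rhsO18 <- rhsO18 - libraryDraw$epsO * log(rDraw)
    rhsSP <- rhsSP - libraryDraw$epsSP * log(rDraw)
  }
  m <- rbind(c(eff$o18, rhsO18),
             c(eff$sp, rhsSP),
             c(1, 1, 0, 0, measurementDraw$spc),
             c(1, 1, 1, 1, 1))
  dimnames(m) <- list(c("o18", "sp", "spc", "norm"),
                      c(N2O_PROCESSES, "rhs"))
  m
}

#' Solve the augmented system for the source fractions
#'
#' Exact linear solve of the 4 x 4 system. The solution automatically
#' satisfies the simplex-sum and SPC identities; fractions may fall outside
#' [0, 1] and are not clipped (the Monte Carlo layer filters them).
#'
#' @param system 4 x 5 augmented matrix from \code{\link{buildSystem}}.
#' @param condMax condition-number threshold beyond which the source set is
#'   treated as degenerate.
#' @return A \code{\linkS4class{PartitionSolution}} (unvalidated fractions
#'   may lie outside [0, 1]; sum and SPC identities hold to 1e-9).
#' @export
solvePartition <- function(system, condMax = 1e12) {
  A <- system[, 1:4, drop = FALSE]
  b <- system[, 5]
  if (!all(is.finite(A)) || kappa(A, exact = TRUE) > condMax)
    stop("degenerate sources: mixing matrix is singular or near-singular")
  f <- solve(A, b)
  resid <- max(abs(A %*% f - b))
  if (resid > 1e-9)
    stop("linear solve failed to meet residual tolerance")
  new("PartitionSolution", fractions = stats::setNames(as.numeric(f), N2O_PROCESSES),
      spc = b[["spc"]])
}

# truncated-normal draws restricted to (lo, hi] by redraw; keeps the number
# of solved systems equal to nDraws
.rtruncRedraw <- function(n, mean, sd, lo = 0, hi = 1) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x > hi)
  guard <- 0
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] > hi]
    guard <- guard + 1
    if (guard > 10000)
      stop("truncated draw failed: distribution has negligible mass in (0, 1]")
  }
  x
}

#' Constrained Monte Carlo source partitioning
#'
#' Draws all 14 model parameters (eight source signatures, two reduction
#' effects, the two emitted-N2O deltas, SPC and R_N2O) independently from
#' normal distributions around their means and SDs, solves the augmented
#' system for each draw, and keeps draws whose four fractions all lie in
#' [0, 1]. SPC and R draws are redrawn into (0, 1] (truncated normal) so
#' every draw yields a solvable system. R_N2O stands in for the microscopic
#' product ratio in the Rayleigh term (the bacteria-dominated linearization);
#' \code{refineR = TRUE} instead iterates r from the bacterial fraction until
#' convergence.
#'
#' Draw order per run (vectorized, fixed for reproducibility): bD.sp, bD.o18,
#' fD.sp, fD.o18, Ni.sp, Ni.o18, nD.sp, nD.o18, epsSP, epsO, sample.sp,
#' sample.o18, SPC, R.
#'
#' @param library a \code{\linkS4class{SourceLibrary}}.
#' @param measurement an \code{\linkS4class{EmittedMeasurement}}.
#' @param scenario "RM" or "MR".
#' @param nDraws number of parameter draws (default 100000).
#' @param seed integer seed.
#' @param refineR if TRUE, per accepted draw re-solve with
#'   r = f_bD / (f_bD + SPC (1 - R) / R) iterated to |dr| < 1e-6.
#' @return A \code{\linkS4class{MonteCarloRun}}.
#' @export
monteCarloPartition <- function(library, measurement, scenario = c("RM", "MR"),
                                nDraws = 100000, seed = 1, refineR = FALSE) {
  scenario <- match.arg(scenario)
  if (nDraws < 1) stop("nDraws must be at least 1")
  stopifnot(validObject(library), validObject(measurement))
  set.seed(seed)
  sig <- library@signatures

  dr <- list()
  for (p in N2O_PROCESSES) {
    i <- match(p, sig$process)
    dr[[paste0(p, ".sp")]] <- stats::rnorm(nDraws, sig$sp_mean[i], sig$sp_sd[i])
    dr[[paste0(p, ".o18")]] <- stats::rnorm(nDraws, sig$o18_mean[i], sig$o18_sd[i])
  }
  epsSP <- stats::rnorm(nDraws, library@epsSP[["mean"]], library@epsSP[["sd"]])
  epsO <- stats::rnorm(nDraws, library@epsO[["mean"]], library@epsO[["sd"]])
  smpSP <- stats::rnorm(nDraws, measurement@spMean, measurement@spSD)
  smpO18 <- stats::rnorm(nDraws, measurement@o18Mean, measurement@o18SD)
  spc <- .rtruncRedraw(nDraws, measurement@spcMean, measurement@spcSD)
  rr <- .rtruncRedraw(nDraws, measurement@rMean, measurement@rSD)

  tol <- 1e-9
  acc <- matrix(NA_real_, nrow = nDraws, ncol = 6,
                dimnames = list(NULL, c(N2O_PROCESSES, "spc", "r")))
  nAcc <- 0L
  reject <- c(negative = 0L, above_one = 0L, singular = 0L)
  for (i in seq_len(nDraws)) {
    ld <- list(sp = c(bD = dr$bD.sp[i], fD = dr$fD.sp[i],
                      Ni = dr$Ni.sp[i], nD = dr$nD.sp[i]),
               o18 = c(bD = dr$bD.o18[i], fD = dr$fD.o18[i],
                       Ni = dr$Ni.o18[i], nD = dr$nD.o18[i]),
               epsSP = epsSP[i], epsO = epsO[i])
    md <- list(sp = smpSP[i], o18 = smpO18[i], spc = spc[i])
    ri <- rr[i]
    f <- tryCatch({
      sol <- solvePartition(buildSystem(ld, md, scenario, ri))
      if (refineR) {
        for (it in 1:50) {
          fb <- sol@fractions[["bD"]]
          rNew <- fb / (fb + spc[i] * (1 - rr[i]) / rr[i])
          if (!is.finite(rNew) || rNew <= 0 || rNew > 1) break
          if (abs(rNew - ri) < 1e-6) { ri <- rNew; break }
          ri <- rNew
          sol <- solvePartition(buildSystem(ld, md, scenario, ri))
        }
      }
      sol@fractions
    }, error = function(e) NULL)
    if (is.null(f)) { reject[["singular"]] <- reject[["singular"]] + 1L; next }
    if (any(f < -tol)) { reject[["negative"]] <- reject[["negative"]] + 1L; next }
    if (any(f > 1 + tol)) { reject[["above_one"]] <- reject[["above_one"]] + 1L; next }
    nAcc <- nAcc + 1L
    acc[nAcc, ] <- c(f, spc[i], ri)
  }
  if (nAcc == 0L)
    stop("no accepted draws; rejection counts: ",
         paste(sprintf("%s=%d", names(reject), reject), collapse = ", "))
  acc <- acc[seq_len(nAcc), , drop = FALSE]
  summ <- rbind(mean = colMeans(acc[, N2O_PROCESSES, drop = FALSE]),
                sd = apply(acc[, N2O_PROCESSES, drop = FALSE], 2, stats::sd))
  new("MonteCarloRun", accepted = acc, nDraws = nDraws,
      acceptanceCount = nAcc, seed = seed, scenario = scenario,
      summary = summ, diagnostics = list(reject = reject, refineR = refineR))
}

#' Consistency check of the product-ratio linearization
#'
#' The linear system replaces the microscopic product ratio r_N2O by the
#' measured macroscopic R_N2O. This check recomputes r from the ensemble
#' mean bacterial fraction and the measured fluxes: under RM,
#' \code{rHat = fbD * N2O_total / (fbD * N2O_total + N2_denitrified)}; under
#' MR the mixture ratio \code{N2O_total / (N2O_total + N2_denitrified)}.
#' Comparing rHat with the R used in the solve validates (or flags) the
#' linearization.
#'
#' @param run a \code{\linkS4class{MonteCarloRun}}.
#' @param fluxes a \code{\linkS4class{FluxSummary}}.
#' @param scenario "RM" or "MR"; defaults to the run's scenario.
#' @return named numeric(2): \code{r_hat} and \code{r_used} (mean of the
#'   accepted R draws).
#' @export
rConsistencyCheck <- function(run, fluxes, scenario = run@scenario) {
  if (run@acceptanceCount == 0) stop("run has no accepted draws")
  if (missing(fluxes) || is.null(fluxes)) {
    warning("no flux data; skipping r consistency check")
    return(c(r_hat = NA_real_, r_used = NA_real_))
  }
  n2o <- fluxes@n2oTotal[["mean"]]
  n2 <- fluxes@n2Denitrified[["mean"]]
  fbD <- run@summary["mean", "bD"]
  rHat <- if (scenario == "RM") microRatioRM(fbD * n2o, n2)
          else microRatioMR(n2o, n2)
  c(r_hat = rHat, r_used = mean(run@accepted[, "r"]))
}
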