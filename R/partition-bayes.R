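# Bayesian mixing-and-fractionation sampler: Metropolis-Hastings over the
# four source fractions (on the probability simplex) and the product ratio
# r_N2O, against three observed dimensions (d15N-SP, d18O, SPC).
#
# The SPC dimension mixes with source values (1, 1, 0, 0) and undergoes no
# fractionation; the Rayleigh term eps * ln(r) applies to the bD source (RM)
# or to the whole mixture (MR). Source-signature and epsilon uncertainty is
# integrated by drawing a fresh library realization at every iteration and
# evaluating current and proposed states against the same draw.

#' Log-likelihood of a mixing/fractionation state
#'
#' Gaussian log-density of the three observed dimensions (SP, d18O, SPC)
#' around the forward-model predictions for a state on the simplex.
#'
#' @param state numeric(5): \code{f_bD, f_fD, f_Ni, f_nD, r}.
#' @param measurement an \code{\linkS4class{EmittedMeasurement}}.
#' @param libraryDraw list with \code{sp}, \code{o18} (named numeric(4)) and
#'   \code{epsSP}, \code{epsO}; one realization of the source library.
#' @param scenario "RM" or "MR".
#' @return log-density; \code{-Inf} for out-of-domain states.
#' @export
logLikelihood <- function(state, measurement, libraryDraw,
                          scenario = c("RM", "MR")) {
  scenario <- match.arg(scenario)
  f <- state[1:4]
  r <- state[5]
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9 || r <= 0 || r > 1)
    return(-Inf)
  pred <- .forwardPredict(f, r, libraryDraw, scenario)
  stats::dnorm(measurement@spMean, pred[["sp"]], measurement@spSD, log = TRUE) +
    stats::dnorm(measurement@o18Mean, pred[["o18"]], measurement@o18SD, log = TRUE) +
    stats::dnorm(measurement@spcMean, pred[["spc"]], measurement@spcSD, log = TRUE)
}

# forward model shared by the sampler and the synthetic generator
.forwardPredict <- function(f, r, libraryDraw, scenario) {
  f <- unname(f)
  shift_sp <- libraryDraw$epsSP * log(r)
  shift_o <- libraryDraw$epsO * log(r)
  sp <- unname(libraryDraw$sp)
  o18 <- unname(libraryDraw$o18)
  if (scenario == "RM") {
    spPred <- sum(f * sp) + f[1] * shift_sp
    oPred <- sum(f * o18) + f[1] * shift_o
  } else {
    spPred <- sum(f * sp) + shift_sp
    oPred <- sum(f * o18) + shift_o
  }
  c(sp = spPred, o18 = oPred, spc = f[1] + f[2])
}

.softmax4 <- function(z3) {
  e <- exp(c(z3, 0) - max(c(z3, 0)))
  e / sum(e)
}

#' Sample the posterior of the source partition and product ratio
#'
#' Metropolis-Hastings chain over (simplex, r) with a uniform Dirichlet(1)
#' prior on the fractions and a uniform prior on r in (0, 1]. Proposals are
#' an additive Gaussian random walk in additive-log-ratio coordinates
#' (Jacobian-corrected) jointly with a reflected Gaussian step on r. Source
#' signatures and reduction effects are redrawn from the library
#' distributions at every iteration.
#'
#' @param measurement an \code{\linkS4class{EmittedMeasurement}}.
#' @param library a \code{\linkS4class{SourceLibrary}}.
#' @param config a \code{\linkS4class{BayesConfig}}.
#' @return A \code{\linkS4class{PosteriorRun}}.
#' @export
samplePosterior <- function(measurement, library, config = bayesConfig()) {
  stopifnot(validObject(measurement), validObject(library), validObject(config))
  set.seed(config@seed)
  nIter <- as.integer(config@nIter)
  scen <- config@scenario
  sig <- library@signatures
  rFree <- length(config@rFixed) == 0L

  # per-iteration library realizations, pre-drawn in fixed order
  libSP <- sapply(seq_len(4), function(i)
    stats::rnorm(nIter, sig$sp_mean[i], sig$sp_sd[i]))
  libO <- sapply(seq_len(4), function(i)
    stats::rnorm(nIter, sig$o18_mean[i], sig$o18_sd[i]))
  epsSP <- stats::rnorm(nIter, library@epsSP[["mean"]], library@epsSP[["sd"]])
  epsO <- stats::rnorm(nIter, library@epsO[["mean"]], library@epsO[["sd"]])

  if (length(config@init)) {
    f <- config@init[1:4]
    z <- log(f[1:3] / f[4])
    r <- if (rFree) config@init[5] else config@rFixed
  } else {
    z <- c(0, 0, 0)                # ALR coordinates; start at the barycentre
    f <- .softmax4(z)
    r <- if (rFree) 0.5 else config@rFixed
  }
  keepFrom <- floor(config@burnIn * nIter) + 1L
  chain <- matrix(NA_real_, nrow = nIter - keepFrom + 1L, ncol = 5,
                  dimnames = list(NULL, c(N2O_PROCESSES, "r")))
  nAcc <- 0L
  sZ <- config@proposalScaleSimplex
  sR <- config@proposalScaleR
  for (i in seq_len(nIter)) {
    ld <- list(sp = stats::setNames(libSP[i, ], N2O_PROCESSES),
               o18 = stats::setNames(libO[i, ], N2O_PROCESSES),
               epsSP = epsSP[i], epsO = epsO[i])
    llCur <- logLikelihood(c(f, r), measurement, ld, scen)
    zProp <- z + stats::rnorm(3, 0, sZ)
    fProp <- .softmax4(zProp)
    rProp <- r
    if (rFree) {
      rProp <- r + stats::rnorm(1, 0, sR)
      # reflect into (0, 1]
      for (g in 1:100) {
        if (rProp > 1) rProp <- 2 - rProp
        else if (rProp < 0) rProp <- -rProp
        else break
      }
      if (rProp <= 0 || rProp > 1) rProp <- r
    }
    llProp <- logLikelihood(c(fProp, rProp), measurement, ld, scen)
    logAlpha <- (llProp + sum(log(fProp))) - (llCur + sum(log(f)))
    if (is.finite(logAlpha) && log(stats::runif(1)) < logAlpha) {
      z <- zProp; f <- fProp; r <- rProp
      nAcc <- nAcc + 1L
    }
    if (i >= keepFrom) chain[i - keepFrom + 1L, ] <- c(f, r)
  }
  accRate <- nAcc / nIter
  if (accRate < 0.001)
    warning(sprintf(paste("Metropolis acceptance rate %.3g%% is below 0.1%%;",
                          "chain has likely not converged. Consider smaller",
                          "proposal scales or wider measurement SDs."),
                    100 * accRate))
  summ <- rbind(mean = colMeans(chain), sd = apply(chain, 2, stats::sd))
  corr <- suppressWarnings(stats::cor(chain))
  new("PosteriorRun", chain = chain, acceptanceRate = accRate,
      burnIn = config@burnIn, seed = config@seed, scenario = scen,
      summary = summ, correlations = corr)
}

#' Summaries, correlations and histogram data of a posterior run
#'
#' @param run a \code{\linkS4class{PosteriorRun}}.
#' @param bins number of histogram bins per variable.
#' @return list with \code{summary} (data.frame of per-variable mean and
#'   SD), \code{correlations} (5 x 5 Pearson matrix; NA where a variable is
#'   constant) and \code{histograms} (per-variable list of breaks/counts).
#' @export
posteriorReport <- function(run, bins = 40) {
  ch <- run@chain
  if (nrow(ch) == 0) stop("empty chain")
  summary <- data.frame(variable = colnames(ch),
                        mean = colMeans(ch),
                        sd = apply(ch, 2, stats::sd),
                        row.names = NULL)
  corr <- suppressWarnings(stats::cor(ch))
  hists <- lapply(colnames(ch), function(v) {
    h <- graphics::hist(ch[, v], breaks = bins, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(hists) <- colnames(ch)
  list(summary = summary, correlations = corr, histograms = hists)
}
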