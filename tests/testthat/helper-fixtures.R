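# shared fixtures built in code

zeroPrecisions <- c(r29 = 0, r30 = 0, r45 = 0, r46 = 0)

zeroNoise <- function() {
  list(gc_ppm = 0, r29 = 0, r30 = 0, r45 = 0, r46 = 0, d_sp = 0, d_o18 = 0)
}

# study-conditions measurement: shipped synthetic stand-in for the emitted-N2O
# summary (deltas forward-generated; SPC and R from the incubation results)
studyMeasurement <- function() {
  readMeasurement(system.file("extdata", "synthetic_measurement.csv",
                              package = "n2opart"))
}

# n uniform random points on the 4-simplex
randomSimplex <- function(n) {
  x <- matrix(stats::rexp(4 * n), ncol = 4)
  x / rowSums(x)
}

# brute-force 2-D numerical root-find for the two-pool model: multi-start
# Newton (pracma::fsolve), keeping the root with a_p in (b, 1) and d in
# (0, 1]; independent of the package's closed form
twoPoolNumericOracle <- function(x1, x2, b = R15_AIR_N2) {
  fn <- function(p) {
    c(p[2] * (2 * p[1] * (1 - p[1]) - 2 * b * (1 - b)) - x1,
      p[2] * (p[1]^2 - b^2) - x2)
  }
  scale <- max(abs(c(x1, x2, 1e-6)))
  B1 <- 2 * b * (1 - b)
  polish <- function(p) {
    for (k in 1:5) {
      J <- rbind(c(p[2] * (2 - 4 * p[1]), 2 * p[1] * (1 - p[1]) - B1),
                 c(2 * p[1] * p[2], p[1]^2 - b^2))
      step <- tryCatch(solve(J, fn(p)), error = function(e) NULL)
      if (is.null(step)) return(p)
      p <- p - step
    }
    p
  }
  for (a0 in c(0.005, 0.02, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 0.97)) {
    for (d0 in c(1e-3, 0.01, 0.1, 0.5, 1)) {
      root <- tryCatch(suppressWarnings(pracma::fsolve(fn, c(a0, d0))$x),
                       error = function(e) NULL)
      if (is.null(root) || max(abs(fn(root))) > 1e-5 * scale) next
      root <- polish(root)
      if (max(abs(fn(root))) < 1e-10 * scale &&
          root[1] > b + 1e-8 && root[1] < 1 && root[2] > 0 && root[2] <= 1 + 1e-6)
        return(root)
    }
  }
  stop("numeric oracle found no physical root")
}

# batch-means Monte Carlo standard error of a chain mean
batchSE <- function(x, nBatch = 25) {
  m <- floor(length(x) / nBatch)
  bm <- colMeans(matrix(x[seq_len(m * nBatch)], nrow = m))
  stats::sd(bm) / sqrt(nBatch)
}

# library with all SDs collapsed to zero (signatures fixed at their means)
pointLibrary <- function(lib = defaultSourceLibrary()) {
  sig <- signatures(lib)
  sig$sp_sd <- 0
  sig$o18_sd <- 0
  new("SourceLibrary", signatures = sig,
      epsSP = c(mean = unname(lib@epsSP["mean"]), sd = 0),
      epsO = c(mean = unname(lib@epsO["mean"]), sd = 0))
}

meansAsDraw <- function(lib) {
  sig <- signatures(lib)
  list(sp = stats::setNames(sig$sp_mean, sig$process),
       o18 = stats::setNames(sig$o18_mean, sig$process),
       epsSP = unname(lib@epsSP["mean"]),
       epsO = unname(lib@epsO["mean"]))
}
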