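# n2opart

Partitioning soil N2O emissions into their microbial sources by combining
natural-abundance N2O isotopocule data with 15N gas-flux constraints.

## The problem

Nitrous oxide from soil is produced by several microbial pathways at once —
bacterial denitrification (bD), fungal denitrification (fD), nitrification
(Ni) and nitrifier denitrification (nD) — and partially consumed again when
bacteria reduce N2O to N2. Natural-abundance isotopocule measurements of
the emitted N2O (site preference δ¹⁵N^SP and δ¹⁸O) constrain the mixture
but cannot, on their own, separate four sources in two isotope dimensions,
especially with the Rayleigh shift ε·ln(r) that reduction imprints on the
residual gas. A parallel ¹⁵N-labeled-nitrate incubation adds two more
observables: the source partitioning coefficient SPC (fraction of emitted
N2O derived from the nitrate pool, equal to f_bD + f_fD) and the
denitrification product ratio R_N2O = N2O/(N2O + N2).

`n2opart` fuses the two data streams. For each scenario — reduction before
mixing (RM) or mixing before reduction (MR) — it builds the augmented
linear system

```
| δ18O_bD*  δ18O_fD  δ18O_Ni  δ18O_nD | δ18O_sample  |
| SP_bD*    SP_fD    SP_Ni    SP_nD   | SP_sample    |
| 1         1        0        0       | SPC          |
| 1         1        1        1       | 1            |
```

(`*` marks where the shift ε·ln r applies under RM; under MR it moves to
the right-hand side) and estimates the fractions two ways:

* **Constrained Monte Carlo** (`monteCarloPartition`): 100,000 draws of all
  14 uncertain inputs, one exact solve per draw, keeping draws whose four
  fractions land in [0, 1].
* **Bayesian MCMC** (`samplePosterior`): Metropolis–Hastings over the
  fraction simplex and r_N2O jointly, with SPC as a third likelihood
  dimension — so r needs no N2 flux data.

Supporting stages: isotopocule algebra (δ-notation, SP/bulk, Rayleigh
shift, background subtraction, soil-water correction), the ¹⁵N gas-flux
pipeline (binomial two-pool inversion of N2/N2O isotopologue ratios to pool
enrichment a_p, pool-derived fractions and fluxes, SPC and R_N2O), and a
forward simulator of the 4-replicate jar incubation for end-to-end
validation.

## Worked example

```r
library(n2opart)

lib  <- defaultSourceLibrary()   # the four source signatures + reduction effects
meas <- readMeasurement(system.file("extdata", "synthetic_measurement.csv",
                                    package = "n2opart"))

run <- monteCarloPartition(lib, meas, scenario = "RM",
                           nDraws = 100000, seed = 42)
run
#> MonteCarloRun (RM scenario): 2967 / 100000 draws accepted (2.97%)
#>   f_bD : 84.7% +/- 6.5%
#>   f_fD : 12.2% +/- 6.5%
#>   f_Ni : 1.5% +/- 1.0%
#>   f_nD : 1.6% +/- 1.0%
```

About 3% of the random parameter draws admit a physically valid partition —
the expected order of magnitude with 14 uncertain parameters — and the
accepted ensemble attributes ~85% of the emitted N2O to bacterial
denitrification, ~12% to fungi, and ~1.5% each to the nitrifier pathways,
with f_bD + f_fD pinned at the measured SPC of 97%.

The Bayesian route, which treats r_N2O as a fifth unknown instead of
plugging in the measured R:

```r
post <- samplePosterior(meas, lib, bayesConfig(nIter = 50000, seed = 42,
                                               scenario = "RM"))
post
#> PosteriorRun (RM scenario): 25000 kept states, acceptance 40.3%
#>   f_bD  : 89.1% +/- 7.6%
#>   f_fD  : 10.4% +/- 7.9%
#>   f_Ni  : 0.5% +/- 2.2%
#>   f_nD  : 0.0% +/- 0.0%
#>   r_N2O : 49.5% +/- 19.9%
```

The two estimators agree within their spreads; the posterior SD of r_N2O is
wide because, with r free, the three observed dimensions leave a
one-parameter family of exact solutions and the data only weight it.
Finally, the linearization check recomputes r from the ensemble's bacterial
fraction and the measured fluxes:

```r
fl <- fluxSummary(n2oTotal = c(2.31, 0.06), n2oDenitrified = c(2.2428, 0.02),
                  n2Denitrified = c(3.26, 0.8), spc = c(0.9709, 0.0067),
                  rMacro = c(0.4157, 0.0494))
rConsistencyCheck(run, fl)
#>     r_hat    r_used
#> 0.3751888 0.4263721
```

The recomputed microscopic ratio (37.5%) sits a few points below the
macroscopic R actually used (42.6%), quantifying how far the r ≈ R
linearization stretches for this bacteria-dominated soil.

The shipped measurement file is a synthetic stand-in (its deltas are
forward-generated from the study-level partition); see the vignette in
`vignettes/` for the model, its assumptions, and what such self-consistency
runs do and do not demonstrate. `inst/scripts/n2opart` offers the same
functionality as a command line (`simulate`, `gasflux`, `partition`,
`report`).

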