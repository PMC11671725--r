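# File I/O and configuration: CSV schemas for the source library, the
# emitted-N2O measurement summary and headspace time series; YAML run
# configuration; JSON/CSV result reports. Internal canonical units: per mil
# for deltas, fractions for ratios; percent appears only at the I/O layer
# under an explicit unit flag.

#' Default source library
#'
#' The literature consensus signatures of the four N2O sources (per mil;
#' delta-18O vs soil water) with SDs derived from the published ranges under
#' the mean +/- 2 SD convention, and the net reduction isotope effects.
#'
#' @return A \code{\linkS4class{SourceLibrary}} with
#'   bD -1.90 +/- 2.8 / 19.20 +/- 1.65, fD 33.50 +/- 3.18 / 47.20 +/- 3.28,
#'   Ni 35.00 +/- 1.68 / 23.50 +/- 3, nD -5.9 +/- 3.88 / 16.8 +/- 1.25
#'   (SP / d18O), eps_SP -5 +/- 1.35, eps_O -15 +/- 5.
#' @export
defaultSourceLibrary <- function() {
  sig <- data.frame(
    process = N2O_PROCESSES,
    sp_mean = c(-1.90, 33.50, 35.00, -5.9),
    sp_sd = c(2.8, 3.18, 1.68, 3.88),
    o18_mean = c(19.20, 47.20, 23.50, 16.8),
    o18_sd = c(1.65, 3.28, 3.00, 1.25),
    stringsAsFactors = FALSE)
  new("SourceLibrary", signatures = sig,
      epsSP = c(mean = -5, sd = 1.35), epsO = c(mean = -15, sd = 5))
}

#' Read a source-signature CSV
#'
#' Expected columns: \code{process} (bD, fD, Ni, nD), \code{sp_mean},
#'   \code{sp_sd}, \code{o18_mean}, \code{o18_sd}. Reduction effects come
#'   from the \code{eps} argument (e.g. the \code{eps_*} entries of a run
#'   config); they default to the shipped values. Unknown columns are
#'   ignored with a warning.
#'
#' @param path CSV file path.
#' @param eps named list/vector with \code{eps_sp_mean}, \code{eps_sp_sd},
#'   \code{eps_o_mean}, \code{eps_o_sd}.
#' @return A \code{\linkS4class{SourceLibrary}}.
#' @export
readSources <- function(path, eps = list(eps_sp_mean = -5, eps_sp_sd = 1.35,
                                         eps_o_mean = -15, eps_o_sd = 5)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("process", "sp_mean", "sp_sd", "o18_mean", "o18_sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sources file is missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  if (anyDuplicated(df$process))
    stop("duplicate process rows in sources file")
  missP <- setdiff(N2O_PROCESSES, df$process)
  if (length(missP))
    stop("sources file is missing process(es): ", paste(missP, collapse = ", "))
  df <- df[match(N2O_PROCESSES, df$process), need]
  rownames(df) <- NULL
  if (any(df$sp_sd < 0) || any(df$o18_sd < 0))
    stop("negative SD in sources file")
  new("SourceLibrary", signatures = df,
      epsSP = c(mean = as.numeric(eps$eps_sp_mean), sd = as.numeric(eps$eps_sp_sd)),
      epsO = c(mean = as.numeric(eps$eps_o_mean), sd = as.numeric(eps$eps_o_sd)))
}

#' Write a SourceLibrary to CSV
#'
#' @param library a \code{\linkS4class{SourceLibrary}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSources <- function(library, path) {
  utils::write.csv(library@signatures, path, row.names = FALSE)
  invisible(path)
}

#' Read an emitted-N2O measurement CSV
#'
#' One-row CSV with columns \code{sp_mean}, \code{sp_sd}, \code{o18_mean},
#' \code{o18_sd}, \code{spc_mean}, \code{spc_sd}, \code{r_mean},
#' \code{r_sd}. An optional \code{ratio_unit} column ("percent" or
#' "fraction") declares the unit of the SPC and R columns; percent values
#' are converted to the internal fraction representation.
#'
#' @param path CSV file path.
#' @return An \code{\linkS4class{EmittedMeasurement}}.
#' @export
readMeasurement <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sp_mean", "sp_sd", "o18_mean", "o18_sd",
            "spc_mean", "spc_sd", "r_mean", "r_sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement file is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) != 1)
    stop("measurement file must have exactly one row")
  scale <- 1
  if ("ratio_unit" %in% names(df)) {
    u <- tolower(df$ratio_unit[1])
    if (u %in% c("percent", "%")) scale <- 1 / 100
    else if (u != "fraction") stop("ratio_unit must be 'percent' or 'fraction'")
  }
  if (any(unlist(df[c("sp_sd", "o18_sd", "spc_sd", "r_sd")]) < 0))
    stop("negative SD in measurement file")
  emittedMeasurement(
    spMean = df$sp_mean, spSD = df$sp_sd,
    o18Mean = df$o18_mean, o18SD = df$o18_sd,
    spcMean = df$spc_mean * scale, spcSD = df$spc_sd * scale,
    rMean = df$r_mean * scale, rSD = df$r_sd * scale)
}

#' Write an EmittedMeasurement to CSV
#'
#' Full-precision round trip: \code{readMeasurement(writeMeasurement(x))}
#' reproduces every numeric field.
#'
#' @param measurement an \code{\linkS4class{EmittedMeasurement}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMeasurement <- function(measurement, path) {
  df <- data.frame(sp_mean = measurement@spMean, sp_sd = measurement@spSD,
                   o18_mean = measurement@o18Mean, o18_sd = measurement@o18SD,
                   spc_mean = measurement@spcMean, spc_sd = measurement@spcSD,
                   r_mean = measurement@rMean, r_sd = measurement@rSD,
                   ratio_unit = "fraction")
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a headspace time-series CSV
#'
#' Columns: \code{replicate}, \code{time_h}, \code{n2o_ppm}, \code{r29},
#' \code{r30}, \code{r45}, \code{r46}.
#'
#' @param path CSV file path.
#' @return validated headspace data.frame.
#' @export
readHeadspace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  checkHeadspace(df)
  df
}

#' Write a headspace table to CSV
#'
#' @param samples headspace data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeHeadspace <- function(samples, path) {
  checkHeadspace(samples)
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.runToList <- function(run) {
  if (is(run, "MonteCarloRun")) {
    list(method = "ls", scenario = run@scenario, seed = run@seed,
         n_draws = run@nDraws, acceptance_count = run@acceptanceCount,
         summary_percent = list(
           mean = as.list(round(100 * run@summary["mean", ], 4)),
           sd = as.list(round(100 * run@summary["sd", ], 4))),
         rejections = as.list(run@diagnostics$reject))
  } else if (is(run, "PosteriorRun")) {
    list(method = "bayes", scenario = run@scenario, seed = run@seed,
         kept_iterations = nrow(run@chain),
         acceptance_rate = run@acceptanceRate,
         summary_percent = list(
           mean = as.list(round(100 * run@summary["mean", ], 4)),
           sd = as.list(round(100 * run@summary["sd", ], 4))),
         correlations = run@correlations)
  } else stop("unsupported run object of class ", class(run))
}

#' Write a machine-readable run report
#'
#' JSON is the canonical output (summaries in percent, acceptance
#' diagnostics, seed and package version); a CSV mirror of the summary table
#' is written alongside when \code{csv = TRUE}. The human-readable summary
#' printed by \code{show()} uses percentages with one decimal.
#'
#' @param run a \code{\linkS4class{MonteCarloRun}} or
#'   \code{\linkS4class{PosteriorRun}}.
#' @param path output JSON path.
#' @param csv also write \code{<path>.csv} with the summary table.
#' @return the path, invisibly.
#' @export
writeReport <- function(run, path, csv = FALSE) {
  payload <- c(list(package = "n2opart",
                    version = as.character(utils::packageVersion("n2opart"))),
               .runToList(run))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (csv) {
    s <- if (is(run, "MonteCarloRun")) run@summary else run@summary
    df <- data.frame(variable = colnames(s),
                     mean_percent = 100 * s["mean", ],
                     sd_percent = 100 * s["sd", ], row.names = NULL)
    utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}
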