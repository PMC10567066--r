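#' Saturation solubility-pH dataset
#'
#' A titration's observed points: pH (concentration scale pcH, or operational
#' electrode readings paH), observed log10 total solubility, the assigned
#' per-point error of log S (default 0.1 log unit), and the background NaCl
#' level of each point.
#'
#' @param pH numeric vector of pH values.
#' @param logS observed log10 total solubility (M).
#' @param sigma assigned standard error of logS per point (log units).
#' @param c_NaCl background NaCl (M) per point (recycled).
#' @param pH_scale \code{"concentration"} (pcH) or \code{"operational"}
#'   (paH, to be standardized with a jH term during refinement).
#' @param temperature degrees Celsius.
#' @param label free-text source label.
#' @return data.frame of class \code{solubility_dataset} with columns
#'   \code{pH, logS, sigma, c_NaCl}.
#' @export
solubility_dataset <- function(pH, logS, sigma = 0.1, c_NaCl,
                               pH_scale = c("concentration", "operational"),
                               temperature = 20, label = "") {
  pH_scale <- match.arg(pH_scale)
  n <- length(pH)
  stopifnot(length(logS) == n, n >= 2)
  sigma <- rep_len(sigma, n)
  c_NaCl <- rep_len(c_NaCl, n)
  if (any(sigma <= 0)) stop("sigmas must be positive")
  out <- data.frame(pH = pH, logS = logS, sigma = sigma, c_NaCl = c_NaCl)
  attr(out, "pH_scale") <- pH_scale
  attr(out, "temperature") <- temperature
  attr(out, "label") <- label
  class(out) <- c("solubility_dataset", "data.frame")
  out
}

#' Read a solubility-pH dataset from delimited text
#'
#' Expects a CSV with header and columns \code{pH, logS, sigma, c_NaCl}
#' (one row per saturation point). A missing \code{sigma} column gets the
#' default assigned error of 0.1 log unit.
#'
#' @param path CSV file path.
#' @param ... passed to \code{\link{solubility_dataset}} (e.g.
#'   \code{pH_scale}).
#' @return a \code{\link{solubility_dataset}}.
#' @export
read_dataset <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("pH", "logS", "c_NaCl")
  if (!all(need %in% names(df)))
    stop("dataset must have columns pH, logS, c_NaCl (and optionally sigma)")
  if (is.null(df$sigma)) df$sigma <- 0.1
  solubility_dataset(df$pH, df$logS, df$sigma, df$c_NaCl, ...)
}

#' Write a solubility-pH dataset as CSV
#'
#' @param x a \code{\link{solubility_dataset}}.
#' @param path output file path.
#' @export
write_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("pH", "logS", "sigma", "c_NaCl")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Read a model configuration (YAML)
#'
#' The configuration lists the equilibrium constants with their reference
#' ionic strength, which constants are free in refinement, the candidate
#' solid set, and the activity-model options. Example:
#' \preformatted{
#' constants: {pKa1: -1.18, pKa2: 7.12, pS0: 8.02, logK2: 9.94,
#'             pKsp_NaHA: 4.31, I_ref: 1.0}
#' free: [pS0, logK2, pKsp_NaHA]
#' solids: [H2A, NaHA]
#' activity: {charged: none, neutral: none, ks: 0.25}
#' }
#'
#' @param path YAML file path.
#' @return list with elements \code{constants}
#'   (\code{\link{eq_constants}}), \code{free}, \code{solids},
#'   \code{activity} (\code{\link{activity_config}}).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constants)) stop("config must have a 'constants' block")
  ko <- do.call(eq_constants, cfg$constants)
  act <- do.call(activity_config, as.list(cfg$activity))
  list(constants = ko,
       free = cfg$free %||% c("pS0", "logK2", "pKsp_NaHA"),
       solids = cfg$solids %||% declared_solids(ko),
       activity = act)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
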