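# Run an expression with a locally seeded RNG, restoring the caller's
# random state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  expr
}

#' Specification for a synthetic solubility-pH dataset
#'
#' Defines the ground truth and design of a simulated saturation
#' solubility-pH titration in the style of the classical bromothymol blue
#' experiment: a fixed NaCl background, pH adjusted over a target range with
#' concentrated (12 M) strong-acid titrant so dilution stays small, a set
#' number of points evenly spaced in pH, and additive Gaussian noise of 0.1
#' log unit on log10 S_T.
#'
#' @param constants true \code{\link{eq_constants}}.
#' @param c_NaCl initial background NaCl (M).
#' @param pH_range target pcH range, within [0.0, 5.4] by default design.
#' @param n number of points, evenly spaced in pH.
#' @param sigma noise standard deviation on log10 S_T (log units).
#' @param jH true electrode junction coefficient (M^-1); when nonzero the
#'   reported pH values are operational readings through the electrode map.
#' @param activity \code{\link{activity_config}} used by the forward model.
#' @param solids candidate solid set.
#' @param titrant_molarity strong-acid stock concentration (M).
#' @param temperature degrees Celsius.
#' @return object of class \code{generator_spec}.
#' @export
generator_spec <- function(constants, c_NaCl, pH_range = c(0.5, 5.4),
                           n = 10, sigma = 0.1, jH = 0,
                           activity = activity_config(),
                           solids = declared_solids(constants),
                           titrant_molarity = 12, temperature = 20) {
  stopifnot(inherits(constants, "eq_constants"), n >= 4, sigma >= 0,
            length(pH_range) == 2, pH_range[1] < pH_range[2])
  structure(list(constants = constants, c_NaCl = c_NaCl,
                 pH_range = pH_range, n = n, sigma = sigma, jH = jH,
                 activity = activity, solids = solids,
                 titrant_molarity = titrant_molarity,
                 temperature = temperature),
            class = "generator_spec")
}

#' Strong-acid titrant schedule for target pH values
#'
#' For each target pcH, the titrant volume fraction needed so the free
#' strong-acid concentration equals 10^-pcH (the dissolved compound, at
#' micromolar levels, is negligible in the proton balance), with exact
#' dilution of the NaCl background by the added volume.
#'
#' @param pcH_targets target hydrogen-ion exponents.
#' @param c_NaCl0 initial NaCl concentration (M).
#' @param titrant_molarity titrant stock concentration (M).
#' @return data.frame with \code{pcH}, diluted \code{c_NaCl}, \code{c_HCl},
#'   and the cumulative titrant volume fraction \code{v_frac} (per unit
#'   initial volume).
#' @export
titrant_schedule <- function(pcH_targets, c_NaCl0, titrant_molarity = 12) {
  c_H <- 10^(-pcH_targets)
  if (any(c_H >= titrant_molarity))
    stop("target pH unreachable with this titrant strength")
  v <- c_H / (titrant_molarity - c_H)      # per unit initial volume
  d <- 1 / (1 + v)
  data.frame(pcH = pcH_targets, c_NaCl = c_NaCl0 * d, c_HCl = c_H,
             v_frac = v)
}

#' Generate a synthetic saturation solubility-pH dataset
#'
#' Computes the titrant schedule for evenly spaced pcH targets, evaluates
#' the noiseless log10 total solubility through the forward speciation model
#' with the spec's activity settings, adds seeded Gaussian noise, and (when
#' the true jH is nonzero) converts the pH column to operational electrode
#' readings. The generating truth travels with the dataset as attribute
#' \code{"truth"} so recovery tests can compare against it. Same spec and
#' seed give a bit-identical dataset.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @param seed integer seed for the noise draws.
#' @return a \code{\link{solubility_dataset}} with attribute \code{"truth"}
#'   (list: \code{constants}, \code{jH}, \code{logS_true}, \code{schedule}).
#' @export
generate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  pcH <- seq(spec$pH_range[1], spec$pH_range[2], length.out = spec$n)
  sched <- titrant_schedule(pcH, spec$c_NaCl, spec$titrant_molarity)
  logS <- logS_T_curve(spec$constants, sched$pcH, sched$c_NaCl,
                       spec$activity, spec$solids, spec$temperature)
  noise <- if (spec$sigma > 0)
    with_seed(seed, stats::rnorm(spec$n, 0, spec$sigma)) else rep(0, spec$n)
  if (spec$jH != 0) {
    pp <- ph_scale_params(jH = spec$jH)
    pH_out <- pcH_to_paH(sched$pcH, pp)
    scale <- "operational"
  } else {
    pH_out <- sched$pcH
    scale <- "concentration"
  }
  # assigned per-point error stays at the default 0.1 when generating
  # noiseless data: the weights must remain positive
  sigma_out <- if (spec$sigma > 0) spec$sigma else 0.1
  out <- solubility_dataset(pH_out, logS + noise, sigma_out, sched$c_NaCl,
                            pH_scale = scale,
                            temperature = spec$temperature,
                            label = sprintf("synthetic %.2g M NaCl seed %d",
                                            spec$c_NaCl, seed))
  attr(out, "truth") <- list(constants = spec$constants, jH = spec$jH,
                             logS_true = logS, schedule = sched,
                             sigma = spec$sigma, seed = seed)
  out
}

#' Generate a synthetic Abraham-descriptor training table
#'
#' Draws descriptor rows uniformly over ranges spanning the chemical space
#' of published salting-out training sets (A in [0, 1.5], B in [0, 2.5],
#' S in [0.3, 3], E in [0, 3.5], V in [0.3, 4.5]; McGowan volumes are
#' strictly positive) and assigns \code{ks} from the linear Abraham model
#' plus Gaussian noise. Used to exercise the PLS refit without shipping
#' third-party data.
#'
#' @param n number of rows (>= 6).
#' @param coefficients generating \code{a0..a5}
#'   (default \code{abraham_coefficients("pls")}).
#' @param noise Gaussian noise s.d. on ks (M^-1).
#' @param seed integer seed.
#' @return data.frame with columns \code{A, B, S, E, V, ks}.
#' @export
generate_descriptor_table <- function(n = 142,
                                      coefficients =
                                        abraham_coefficients("pls"),
                                      noise = 0.05, seed = 1) {
  stopifnot(n >= 6)
  with_seed(seed, {
    X <- cbind(A = stats::runif(n, 0, 1.5), B = stats::runif(n, 0, 2.5),
               S = stats::runif(n, 0.3, 3), E = stats::runif(n, 0, 3.5),
               V = stats::runif(n, 0.3, 4.5))
    ks <- coefficients["a0"] +
      as.vector(X %*% unname(coefficients[paste0("a", 1:5)])) +
      stats::rnorm(n, 0, noise)
    data.frame(X, ks = ks)
  })
}
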