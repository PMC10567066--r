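#' Equilibrium constant set for a self-associating diprotic acid
#'
#' Bundles the refinable thermodynamic parameters of the speciation model:
#' the two macroscopic ionization constants of the diprotic acid H2A, the
#' intrinsic (neutral monomer) solubility, the neutral dimerization constant
#' K2 = [H4A2]/[H2A]^2, the solubility product of the sodium salt of the
#' monoanion, and optionally the mixed-charge dimer H2A.HA- and its sodium
#' salt solid. All constants are concentration quotients on the constant
#' ionic medium (CIM) scale, referenced to the ionic strength \code{I_ref}
#' (and, for neutral-species salting, to the salt level \code{Cs_ref}).
#'
#' @param pKa1 first ionization constant, -log10([H+][HA-]/[H2A]).
#' @param pKa2 second ionization constant, -log10([H+][A2-]/[HA-]).
#' @param pS0 -log10 intrinsic solubility of the neutral monomer (M).
#' @param logK2 log10 neutral dimerization constant (M^-1); \code{-Inf}
#'   disables the dimer.
#' @param pKsp_NaHA -log10 of Ksp = [Na+][HA-] (M^2); \code{NA} disables the
#'   NaHA(s) solid.
#' @param logK_H3A2 log10 formation constant of the mixed dimer
#'   H2A + HA- = H3A2- (M^-1); \code{NA} disables the species.
#' @param pKps_NaH3A2 -log10 of Kps = [Na+][H3A2-] (M^2) for the salt solid
#'   NaH3A2(s); \code{NA} disables it.
#' @param I_ref reference ionic strength (M) of the CIM scale.
#' @param Cs_ref reference salt concentration (M) for neutral-species
#'   salting corrections (defaults to \code{I_ref}).
#' @return an object of class \code{eq_constants}.
#' @examples
#' k <- eq_constants(pKa1 = -1.18, pS0 = 8.02, logK2 = 9.94,
#'                   pKsp_NaHA = 4.31, I_ref = 1.0)
#' print(k)
#' @export
eq_constants <- function(pKa1, pKa2 = 7.12, pS0, logK2 = -Inf,
                         pKsp_NaHA = NA_real_, logK_H3A2 = NA_real_,
                         pKps_NaH3A2 = NA_real_, I_ref = 1.0,
                         Cs_ref = NULL) {
  stopifnot(is.numeric(pKa1), is.numeric(pKa2), is.numeric(pS0))
  if (!(pKa1 < pKa2))
    stop("pKa1 must be smaller than pKa2")
  if (!is.na(pKps_NaH3A2) && is.na(logK_H3A2))
    stop("NaH3A2(s) requires the mixed dimer H3A2- (logK_H3A2)")
  if (is.null(Cs_ref)) Cs_ref <- I_ref
  structure(list(pKa1 = pKa1, pKa2 = pKa2, pS0 = pS0, logK2 = logK2,
                 pKsp_NaHA = pKsp_NaHA, logK_H3A2 = logK_H3A2,
                 pKps_NaH3A2 = pKps_NaH3A2, I_ref = I_ref, Cs_ref = Cs_ref),
            class = "eq_constants")
}

#' @export
print.eq_constants <- function(x, ...) {
  cat("Equilibrium constants (CIM scale, I_ref =", x$I_ref, "M)\n")
  flds <- c("pKa1", "pKa2", "pS0", "logK2", "pKsp_NaHA",
            "logK_H3A2", "pKps_NaH3A2")
  for (f in flds)
    if (is.finite(x[[f]]) || !is.na(x[[f]]))
      cat(sprintf("  %-12s %8.3f\n", f, x[[f]]))
  invisible(x)
}

# Update selected constants, keeping the class and reference tags.
update_constants <- function(constants, values) {
  for (nm in names(values)) constants[[nm]] <- unname(values[[nm]])
  constants
}

#' Published equilibrium constant sets for bromothymol blue
#'
#' Refined constant sets for bromothymol blue (BTB) at 20 degrees C in NaCl
#' media. The model-C sets carry pKa1 = -1.18 on the I_ref = 1.0 M CIM scale
#' (the independently measured -0.66 at I = 4.59 M re-referenced by the
#' Stokes-Robinson hydration correction). The model-A sets are the dimer-free
#' alternative with pKa1 = 1.43 at I_ref = 0.1 M; in 1.0 M NaCl that model
#' needs the mixed dimer H2A.HA- and a second salt solid NaH3A2(s).
#'
#' @param medium background NaCl concentration label, \code{"0.1"} or
#'   \code{"1.0"} (M).
#' @param model model strategy label, \code{"C"} (neutral dimer, single
#'   independent pKa1) or \code{"A"} (dimer-free high-salting alternative).
#' @return an \code{\link{eq_constants}} object.
#' @export
btb_constants <- function(medium = c("0.1", "1.0"), model = c("C", "A")) {
  medium <- match.arg(medium)
  model <- match.arg(model)
  if (model == "C") {
    if (medium == "0.1")
      eq_constants(pKa1 = -1.18, pKa2 = 7.12, pS0 = 8.03, logK2 = 10.11,
                   pKsp_NaHA = 4.41, I_ref = 1.0, Cs_ref = 0.1)
    else
      eq_constants(pKa1 = -1.18, pKa2 = 7.12, pS0 = 8.02, logK2 = 9.94,
                   pKsp_NaHA = 4.31, I_ref = 1.0, Cs_ref = 1.0)
  } else {
    if (medium == "0.1")
      eq_constants(pKa1 = 1.43, pKa2 = 7.12, pS0 = 5.17, logK2 = -Inf,
                   pKsp_NaHA = 4.41, I_ref = 0.1, Cs_ref = 0.1)
    else
      eq_constants(pKa1 = 1.43, pKa2 = 7.12, pS0 = 5.17, logK2 = -Inf,
                   pKsp_NaHA = 4.33, logK_H3A2 = 5.87, pKps_NaH3A2 = 4.93,
                   I_ref = 0.1, Cs_ref = 1.0)
  }
}

#' Abraham-model coefficients for salting-out prediction
#'
#' Coefficient sets (M^-1 scale) of the linear free-energy relationship
#' ks = a0 + a1*A + a2*B + a3*S + a4*E + a5*V used to predict Setschenow
#' salting-out constants from Abraham solvation descriptors. \code{"endo"}
#' is the multi-linear-regression set of Endo and co-workers; \code{"pls"}
#' is the partial-least-squares refit on the extended 142-compound training
#' compilation.
#'
#' @param set which coefficient set, \code{"endo"} or \code{"pls"}.
#' @return named numeric vector \code{c(a0, a1, a2, a3, a4, a5)}.
#' @export
abraham_coefficients <- function(set = c("endo", "pls")) {
  set <- match.arg(set)
  if (set == "endo")
    c(a0 = 0.112, a1 = -0.047, a2 = -0.060, a3 = -0.042, a4 = -0.020,
      a5 = 0.171)
  else
    c(a0 = 0.090, a1 = -0.073, a2 = -0.064, a3 = -0.039, a4 = -0.002,
      a5 = 0.188)
}

#' Abraham solvation descriptors of bromothymol blue
#'
#' ABSOLV-calculated descriptors of the neutral (zwitterionic) form:
#' H-bond acidity A, H-bond basicity B, dipolarity/polarizability S,
#' excess molar refractivity E ((cm^3/mol)/10), and McGowan volume V
#' ((cm^3/mol)/100).
#'
#' @return named numeric vector \code{c(A, B, S, E, V)}.
#' @export
btb_descriptors <- function() {
  c(A = 0.33, B = 1.28, S = 2.48, E = 2.94, V = 3.99)
}
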