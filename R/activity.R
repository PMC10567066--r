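#' Debye-Huckel A and B coefficients
#'
#' Limiting-law coefficients for water at the working temperature, from the
#' static dielectric constant of water (Malmberg-Maryott polynomial).
#' A is in (mol/L)^-1/2 (log10 basis), B in Angstrom^-1 (mol/L)^-1/2.
#'
#' @param temp_C temperature in degrees Celsius.
#' @return named vector \code{c(A, B)}.
#' @export
debye_huckel_AB <- function(temp_C = 20) {
  eps <- 87.74 - 0.4008 * temp_C + 9.398e-4 * temp_C^2 - 1.41e-6 * temp_C^3
  TK <- temp_C + 273.15
  c(A = 1.8246e6 / (eps * TK)^1.5, B = 50.29 / sqrt(eps * TK))
}

#' Hydration parameters for the Stokes-Robinson activity model
#'
#' Parameter set of the Stokes-Robinson hydration equation for a 1:1
#' background electrolyte: ion-size parameter \code{a} (Angstrom), hydration
#' number \code{h}, stoichiometric ion count \code{nu}, and temperature.
#' The \code{"HCl"} set (a = 4.47 A) carries h = 6.09, calibrated once so the
#' proton-ionization correction maps a pKa of -0.66 at I = 4.59 M to -1.18 at
#' I = 1.0 M; it is used for ionization-type reactions involving H+. The
#' \code{"NaCl"} set (a = 4.0 A, h = 3.5, the standard Robinson-Stokes
#' tabulation) is used for the sodium-salt solubility product. With h = 0 the
#' model reduces to the extended Debye-Huckel expression.
#'
#' @param electrolyte \code{"HCl"}, \code{"NaCl"}, or \code{"custom"}.
#' @param a ion-size parameter (Angstrom), for \code{"custom"}.
#' @param h hydration number, for \code{"custom"}.
#' @param temp_C temperature (degrees C); the study condition is 20 C.
#' @return object of class \code{hydration_params}.
#' @export
hydration_params <- function(electrolyte = c("HCl", "NaCl", "custom"),
                             a = NULL, h = NULL, temp_C = 20) {
  electrolyte <- match.arg(electrolyte)
  if (electrolyte == "HCl") { a <- 4.47; h <- 6.09 }
  if (electrolyte == "NaCl") { a <- 4.0; h <- 3.5 }
  stopifnot(!is.null(a), !is.null(h), a > 0, h >= 0)
  AB <- debye_huckel_AB(temp_C)
  structure(list(electrolyte = electrolyte, a = a, h = h, nu = 2,
                 temp_C = temp_C, A = unname(AB["A"]), B = unname(AB["B"])),
            class = "hydration_params")
}

#' Per-unit-charge log10 activity coefficient (Stokes-Robinson)
#'
#' The mean ionic activity coefficient of a 1:1 electrolyte in the
#' Stokes-Robinson hydration model,
#' \deqn{\log\gamma_\pm = -\frac{A\sqrt I}{1 + Ba\sqrt I}
#'   - \frac{h}{\nu}\log a_w - \log(1 - 0.018(h-\nu) m)}
#' with water activity taken as ideal (\eqn{\ln a_w = -0.018\,\nu m}) and
#' molality approximated by molarity. A single unit-charge ion is assigned
#' \eqn{\log\gamma_i = \log\gamma_\pm}; an ion of charge z scales as z^2.
#' Valid up to about I = 5 M; a warning is issued beyond that.
#'
#' @param I ionic strength(s) (M), > 0.
#' @param params \code{\link{hydration_params}}.
#' @return log10 gamma per unit squared charge.
#' @export
sr_log_gamma <- function(I, params = hydration_params("HCl")) {
  if (any(I <= 0)) stop("ionic strength must be positive")
  if (any(I > 5))
    warning("Stokes-Robinson correction applied beyond its I < 5 M range")
  log_aw <- -0.018 * params$nu * I / log(10)
  dh <- -params$A * sqrt(I) / (1 + params$B * params$a * sqrt(I))
  dh - (params$h / params$nu) * log_aw -
    log10(1 - 0.018 * (params$h - params$nu) * I)
}

#' Re-reference a pK between ionic strengths (Stokes-Robinson)
#'
#' Converts a concentration-quotient pK from one ionic strength to another on
#' the constant-ionic-medium scale. For a reaction with product charges
#' \code{z_products} and reactant charges \code{z_reactants} (solids and
#' neutral species enter with charge 0 and receive no correction),
#' \deqn{pK(I_{to}) = pK(I_{from}) + \Delta z^2\,[g(I_{to}) - g(I_{from})]}
#' where \eqn{\Delta z^2 = \sum_{prod} z^2 - \sum_{react} z^2} and g is
#' \code{\link{sr_log_gamma}}. Identity when \code{I_from == I_to}; reduces
#' to the extended Debye-Huckel correction when \code{params$h == 0}.
#'
#' @param pK the constant to convert (-log10 of a concentration quotient).
#' @param z_products integer charges of the product species.
#' @param z_reactants integer charges of the reactant species.
#' @param I_from,I_to source and destination ionic strengths (M).
#' @param params \code{\link{hydration_params}}.
#' @return the re-referenced pK.
#' @examples
#' # proton ionization H2A = H+ + HA-, from 4.59 M to the 1.0 M CIM scale
#' stokes_robinson_adjust(-0.66, c(1, -1), 0, 4.59, 1.0)
#' @export
stokes_robinson_adjust <- function(pK, z_products, z_reactants,
                                   I_from, I_to,
                                   params = hydration_params("HCl")) {
  if (I_from == I_to) return(pK)
  dz2 <- sum(z_products^2) - sum(z_reactants^2)
  if (dz2 == 0) return(pK)
  pK + dz2 * (sr_log_gamma(I_to, params) - sr_log_gamma(I_from, params))
}

#' Setschenow adjustment of a neutral-species log constant
#'
#' Shifts a log10 quantity of a neutral species (a log solubility, or any
#' log constant whose net neutral-solute stoichiometry is 1) between salt
#' concentrations: \code{log_value - ks * (Cs_to - Cs_from)}. A positive ks
#' (salting-out) lowers the solubility as salt is added.
#'
#' @param log_value log10 value at \code{Cs_from} (e.g. log10 S0, not pS0).
#' @param Cs_from,Cs_to source and destination salt concentrations (M).
#' @param ks Setschenow salting parameter (M^-1).
#' @return the adjusted log10 value.
#' @export
setschenow_adjust <- function(log_value, Cs_from, Cs_to, ks) {
  stopifnot(Cs_from >= 0, Cs_to >= 0)
  log_value - ks * (Cs_to - Cs_from)
}

#' Self-interaction constant from the modified Setschenow equation
#'
#' When the solute self-associates, the empirical Setschenow constant
#' derived from total solubilities differs from the true salting parameter
#' ks; the modified form attributes the excess to a solute self-interaction
#' term:
#' \deqn{\log_{10}(S_{T(0)}/S_{T(s)}) = k_s C_s + k_{self}(S_{T(s)} - S_{T(0)})}
#' so \eqn{k_{self} = [\log_{10}(S_{T(0)}/S_{T(s)}) - k_s C_s] /
#' (S_{T(s)} - S_{T(0)})}. Only for low total solubility, or with no
#' self-interaction, does the empirical constant equal ks. A negative
#' k_self under this parameterization means association decreases as salt
#' is added.
#'
#' @param ks true salting parameter (M^-1).
#' @param Cs salt concentration (M) of the salted medium.
#' @param S_T0 total solubility in the salt-free medium (M).
#' @param S_Ts total solubility in the salted medium (M).
#' @return self-interaction constant k_self (M^-1).
#' @examples
#' # empirical line pS_T = 5.10 + 0.778 Cs, true ks = 0.250, Cs = 1 M
#' self_interaction_solve(0.250, 1.0, 10^-5.10, 10^-5.878)
#' @export
self_interaction_solve <- function(ks, Cs, S_T0, S_Ts) {
  stopifnot(S_T0 > 0, S_Ts > 0, Cs >= 0)
  if (S_T0 == S_Ts)
    stop("S_T0 == S_Ts: self-interaction constant is undefined")
  (log10(S_T0 / S_Ts) - ks * Cs) / (S_Ts - S_T0)
}

#' Activity-correction configuration
#'
#' Selects how equilibrium constants are adjusted for local deviations from
#' their reference conditions during speciation: charged-species constants
#' by ionic strength (\code{"none"}, \code{"debye_huckel"}, or
#' \code{"stokes_robinson"}) and neutral-species constants by salt level
#' (\code{"none"}, \code{"setschenow"}, or \code{"setschenow_self"}).
#' Under \code{"setschenow"} the intrinsic solubility is shifted by
#' \code{ks} per molar salt and the dimerization constant by
#' \code{2*ks - ks_dimer}; the default \code{ks_dimer = 2*ks}
#' (volume-proportional salting of the dimer) leaves K2 salt-independent.
#' The salt level seen by a point is the added background salt (NaCl,
#' after dilution); set \code{salt_source = "background_plus_titrant"} to
#' count the strong-acid titrant as salt too, relevant when working below
#' pH 0 where HCl levels rival the background.
#'
#' @param charged ionic-strength correction scheme for charged species.
#' @param neutral salting correction scheme for neutral species.
#' @param ks neutral monomer Setschenow parameter (M^-1).
#' @param ks_dimer neutral dimer Setschenow parameter (M^-1).
#' @param k_self self-interaction parameter (M^-1), used by
#'   \code{"setschenow_self"}.
#' @param salt_source which electrolytes count toward the Setschenow salt
#'   concentration Cs.
#' @param params_acid hydration parameters for ionization-type reactions.
#' @param params_salt hydration parameters for the sodium-salt Ksp.
#' @return object of class \code{activity_config}.
#' @export
activity_config <- function(charged = c("none", "debye_huckel",
                                        "stokes_robinson"),
                            neutral = c("none", "setschenow",
                                        "setschenow_self"),
                            ks = 0.25, ks_dimer = 2 * ks, k_self = 0,
                            salt_source = c("background",
                                            "background_plus_titrant"),
                            params_acid = hydration_params("HCl"),
                            params_salt = hydration_params("NaCl")) {
  charged <- match.arg(charged)
  neutral <- match.arg(neutral)
  salt_source <- match.arg(salt_source)
  if (charged == "debye_huckel") {
    params_acid <- hydration_params("custom", a = params_acid$a, h = 0,
                                    temp_C = params_acid$temp_C)
    params_salt <- hydration_params("custom", a = params_salt$a, h = 0,
                                    temp_C = params_salt$temp_C)
  }
  structure(list(charged = charged, neutral = neutral, ks = ks,
                 ks_dimer = ks_dimer, k_self = k_self,
                 salt_source = salt_source,
                 params_acid = params_acid, params_salt = params_salt),
            class = "activity_config")
}
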