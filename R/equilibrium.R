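#' Solution composition of a titration point
#'
#' Background medium of one saturation point: the NaCl level, optionally the
#' cumulative strong-acid titrant concentration (after dilution), and the
#' temperature. When \code{c_HCl} is \code{NA} it is inferred from charge
#' balance at the stated pcH during speciation.
#'
#' @param c_NaCl background NaCl concentration (M).
#' @param c_HCl cumulative HCl titrant concentration (M), or \code{NA}.
#' @param temperature degrees Celsius.
#' @return object of class \code{solution_composition}.
#' @export
solution_composition <- function(c_NaCl, c_HCl = NA_real_, temperature = 20) {
  stopifnot(c_NaCl >= 0, is.na(c_HCl) || c_HCl >= 0)
  structure(list(c_NaCl = c_NaCl, c_HCl = c_HCl, temperature = temperature),
            class = "solution_composition")
}

# Concentration floor keeping logarithms finite for absent species.
.conc_floor <- 1e-30
.pKw <- 14.17

# Candidate solids declared by a constant set.
declared_solids <- function(constants) {
  s <- "H2A"
  if (!is.na(constants$pKsp_NaHA)) s <- c(s, "NaHA")
  if (!is.na(constants$pKps_NaH3A2)) s <- c(s, "NaH3A2")
  s
}

# Adjust a constant set from its reference conditions to local ionic
# strength I and salt level Cs, per the activity configuration. Returns
# linear-scale constants.
local_constants <- function(constants, I, Cs, activity) {
  pKa1 <- constants$pKa1; pKa2 <- constants$pKa2
  pS0 <- constants$pS0; logK2 <- constants$logK2
  pKsp <- constants$pKsp_NaHA; pKps <- constants$pKps_NaH3A2
  if (activity$charged != "none" && I != constants$I_ref) {
    pKa1 <- stokes_robinson_adjust(pKa1, c(1, -1), 0, constants$I_ref, I,
                                   activity$params_acid)
    pKa2 <- stokes_robinson_adjust(pKa2, c(1, -2), -1, constants$I_ref, I,
                                   activity$params_acid)
    if (!is.na(pKsp))
      pKsp <- stokes_robinson_adjust(pKsp, c(1, -1), 0, constants$I_ref, I,
                                     activity$params_salt)
    if (!is.na(pKps))
      pKps <- stokes_robinson_adjust(pKps, c(1, -1), 0, constants$I_ref, I,
                                     activity$params_salt)
    # mixed-dimer formation H2A + HA- = H3A2-: delta z^2 = 0, no correction
  }
  if (activity$neutral != "none" && Cs != constants$Cs_ref) {
    dCs <- Cs - constants$Cs_ref
    pS0 <- pS0 + activity$ks * dCs
    if (is.finite(logK2))
      logK2 <- logK2 + (2 * activity$ks - activity$ks_dimer) * dCs
  }
  list(Ka1 = 10^(-pKa1), Ka2 = 10^(-pKa2), S0 = 10^(-pS0),
       K2 = if (is.finite(logK2)) 10^logK2 else 0,
       Ksp = if (is.na(pKsp)) NA_real_ else 10^(-pKsp),
       KH3A2 = if (is.na(constants$logK_H3A2)) 0
               else 10^constants$logK_H3A2,
       Kps = if (is.na(pKps)) NA_real_ else 10^(-pKps))
}

# Saturated-solution speciation for given local constants, sodium level and
# [H+]. The controlling solid is the candidate imposing the lowest neutral
# monomer concentration (equivalently the lowest total solubility), which
# leaves no other candidate supersaturated.
speciate_core <- function(loc, Na, h, solids) {
  lim <- c(H2A = if ("H2A" %in% solids) loc$S0 else Inf,
           NaHA = if ("NaHA" %in% solids && !is.na(loc$Ksp))
                    h * loc$Ksp / (Na * loc$Ka1) else Inf,
           NaH3A2 = if ("NaH3A2" %in% solids && !is.na(loc$Kps) &&
                        loc$KH3A2 > 0)
                      sqrt(loc$Kps * h / (Na * loc$KH3A2 * loc$Ka1))
                    else Inf)
  h2a <- min(lim)
  if (!is.finite(h2a)) stop("no candidate solid phase declared")
  controlling <- names(lim)[lim <= h2a * (1 + 1e-9)]
  ha <- loc$Ka1 * h2a / h
  a2 <- loc$Ka2 * ha / h
  h4a2 <- loc$K2 * h2a^2
  h3a2 <- loc$KH3A2 * h2a * ha
  conc <- pmax(c(H2A = h2a, HA = ha, A2 = a2, H4A2 = h4a2, H3A2 = h3a2),
               .conc_floor)
  S_T <- conc[["H2A"]] + conc[["HA"]] + conc[["A2"]] +
    2 * conc[["H4A2"]] + 2 * conc[["H3A2"]]
  list(conc = conc, S_T = S_T, controlling = controlling)
}

#' Solve the saturated speciation at one pH point
#'
#' Given a constant set, the medium and the hydrogen-ion concentration
#' exponent pcH, computes the concentrations of all aqueous species
#' (H2A, HA-, A2-, the neutral dimer H4A2 and, if modeled, the mixed dimer
#' H3A2-), selects the controlling solid phase(s), and returns the total
#' solubility in monomer equivalents,
#' \deqn{S_T = [H_2A] + [HA^-] + [A^{2-}] + 2[H_4A_2] + 2[H_3A_2^-].}
#' Constants are adjusted to the point's local ionic strength and salt level
#' per \code{activity}; the ionic strength is made self-consistent with the
#' speciation by fixed-point iteration (relative tolerance 1e-8, at most 200
#' iterations — species concentrations are tiny against the 0.1-1 M
#' background, so this converges in a few passes).
#'
#' @param constants \code{\link{eq_constants}}.
#' @param medium \code{\link{solution_composition}}.
#' @param pcH -log10 [H+], in [-1.5, 7].
#' @param activity \code{\link{activity_config}}.
#' @param solids candidate solid phases (subset of \code{"H2A"},
#'   \code{"NaHA"}, \code{"NaH3A2"}); default: all declared by
#'   \code{constants}.
#' @return object of class \code{speciation_result}: species concentrations,
#'   \code{S_T}, \code{logS_T}, mole \code{fractions} of dissolved compound,
#'   \code{controlling_solids}, local ionic strength \code{I}, salt level
#'   \code{Cs}, and the inferred titrant level \code{c_HCl}.
#' @examples
#' k <- btb_constants("1.0")
#' solve_point(k, solution_composition(1.0), pcH = 0.60)
#' @export
solve_point <- function(constants, medium, pcH,
                        activity = activity_config(),
                        solids = declared_solids(constants)) {
  stopifnot(inherits(constants, "eq_constants"),
            inherits(medium, "solution_composition"))
  if (pcH < -1.5 || pcH > 7)
    stop("pcH outside the supported range [-1.5, 7]")
  solids <- match.arg(solids, c("H2A", "NaHA", "NaH3A2"),
                      several.ok = TRUE)
  h <- 10^(-pcH)
  oh <- 10^(pcH - .pKw)
  Na <- medium$c_NaCl
  if (Na <= 0) Na <- .conc_floor  # salt solids then never control
  c_HCl <- if (is.na(medium$c_HCl)) h else medium$c_HCl
  I <- Na + 0.5 * (h + (Na + c_HCl) + oh)
  # fully consistent only after speciation; iterate
  needs_iter <- activity$charged != "none" || activity$neutral != "none"
  sp <- NULL
  for (iter in seq_len(200)) {
    Cs <- if (identical(activity$salt_source, "background_plus_titrant"))
      Na + c_HCl else Na
    loc <- local_constants(constants, I, Cs, activity)
    sp <- speciate_core(loc, Na, h, solids)
    cc <- sp$conc
    if (is.na(medium$c_HCl))
      c_HCl <- max(0, h - oh + cc[["HA"]] + 2 * cc[["A2"]] + cc[["H3A2"]])
    cl <- Na + c_HCl
    I_new <- 0.5 * (Na + cl + h + oh + cc[["HA"]] + 4 * cc[["A2"]] +
                    cc[["H3A2"]])
    done <- abs(I_new - I) <= 1e-8 * max(I, 1e-12)
    I <- I_new
    if (done || !needs_iter) break
    if (iter == 200)
      stop(sprintf(paste0("ionic-strength iteration did not converge; ",
                          "last iterate I = %.8g M"), I))
  }
  fr <- sp$conc * c(1, 1, 1, 2, 2) / sp$S_T
  Cs <- if (identical(activity$salt_source, "background_plus_titrant"))
    Na + c_HCl else Na
  structure(list(concentrations = sp$conc, S_T = sp$S_T,
                 logS_T = log10(sp$S_T), fractions = fr, pcH = pcH,
                 I = I, Cs = Cs, c_HCl = c_HCl,
                 controlling_solids = sp$controlling),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("Saturated speciation at pcH %.3f (I = %.3f M)\n", x$pcH, x$I))
  cat(sprintf("  controlling solid(s): %s\n",
              paste(x$controlling_solids, collapse = " + ")))
  for (s in names(x$concentrations))
    cat(sprintf("  [%-5s] = %10.4g M  (fraction %.4f)\n", s,
                x$concentrations[[s]], x$fractions[[s]]))
  cat(sprintf("  S_T = %.4g M (log10 = %.4f)\n", x$S_T, x$logS_T))
  invisible(x)
}

#' Controlling solid phase(s) at a pH point
#'
#' Returns the solid(s) whose saturation condition yields the lowest total
#' solubility, leaving no supersaturation with respect to any other declared
#' candidate; at a crossover pH two solids co-control.
#'
#' @inheritParams solve_point
#' @return character vector of controlling solids.
#' @export
select_solid_phase <- function(constants, medium, pcH,
                               activity = activity_config(),
                               solids = declared_solids(constants)) {
  solve_point(constants, medium, pcH, activity, solids)$controlling_solids
}

#' Log total solubility curve over a pH vector
#'
#' Vector forward model used by the refinement and generator layers: for
#' each point i, evaluates \code{solve_point} at \code{pcH[i]} in medium
#' \code{c_NaCl[i]} and returns log10 S_T.
#'
#' @param constants \code{\link{eq_constants}}.
#' @param pcH numeric vector of hydrogen-ion exponents.
#' @param c_NaCl background NaCl per point (recycled if length 1).
#' @param activity \code{\link{activity_config}}.
#' @param solids candidate solids.
#' @param temperature degrees Celsius.
#' @return numeric vector of log10 total solubility.
#' @export
logS_T_curve <- function(constants, pcH, c_NaCl,
                         activity = activity_config(),
                         solids = declared_solids(constants),
                         temperature = 20) {
  c_NaCl <- rep_len(c_NaCl, length(pcH))
  vapply(seq_along(pcH), function(i) {
    solve_point(constants,
                solution_composition(c_NaCl[i], temperature = temperature),
                pcH[i], activity, solids)$logS_T
  }, numeric(1))
}

#' Approximate pKa1 from the anion/dimer half-point
#'
#' In a saturated solution where the neutral mass is dominated by the dimer,
#' the pH at which the monoanion holds half the dissolved compound
#' ([HA-] = [H4A2] in monomer units) back-estimates the first ionization
#' constant as \code{-log10(2) + pcH_half + pS0 - logK2}.
#'
#' @param pcH_half half-point pH on the concentration scale.
#' @param pS0 -log10 intrinsic solubility.
#' @param logK2 log10 dimerization constant.
#' @return approximate pKa1.
#' @export
halfpoint_pKa1_estimate <- function(pcH_half, pS0, logK2) {
  -log10(2) + pcH_half + pS0 - logK2
}

#' Distribution of dissolved species across a pH grid
#'
#' Mole fractions of the total dissolved compound held by each species at
#' each grid point, with the controlling solid and total solubility, plus
#' the pH where the monoanion fraction crosses one half (linear
#' interpolation between grid points), returned as attribute
#' \code{"pH_half"}.
#'
#' @param constants \code{\link{eq_constants}}.
#' @param medium \code{\link{solution_composition}}.
#' @param pH_grid sorted vector of pcH values.
#' @param activity \code{\link{activity_config}}.
#' @param solids candidate solids.
#' @return data.frame with columns \code{pcH}, one fraction column per
#'   species, \code{logS_T} and \code{solid}.
#' @export
species_distribution <- function(constants, medium, pH_grid,
                                 activity = activity_config(),
                                 solids = declared_solids(constants)) {
  if (is.unsorted(pH_grid)) stop("pH_grid must be sorted increasing")
  rows <- lapply(pH_grid, function(p)
    solve_point(constants, medium, p, activity, solids))
  fr <- do.call(rbind, lapply(rows, function(r) r$fractions))
  out <- data.frame(pcH = pH_grid, fr,
                    logS_T = vapply(rows, `[[`, numeric(1), "logS_T"),
                    solid = vapply(rows, function(r)
                      paste(r$controlling_solids, collapse = "+"),
                      character(1)))
  an <- out$HA
  cross <- which(diff(sign(an - 0.5)) != 0)
  pH_half <- vapply(cross, function(i) {
    stats::approx(an[c(i, i + 1)], pH_grid[c(i, i + 1)], xout = 0.5)$y
  }, numeric(1))
  attr(out, "pH_half") <- pH_half
  out
}
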