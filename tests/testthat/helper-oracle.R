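# Brute-force saturation solver, independent of the package's closed-form
# speciation path. Finds the neutral-monomer concentration by bisection on
# the maximum supersaturation ratio over the declared solids, then sums the
# species. Optionally includes a hypothetical anion dimer (HA-)2 with
# formation constant K22 = [H2A2^2-]/[HA-]^2, which the package model does
# not carry, for slope-discrimination checks.
oracle_solve <- function(constants, Na, pcH, logK22 = -Inf) {
  h <- 10^(-pcH)
  Ka1 <- 10^(-constants$pKa1); Ka2 <- 10^(-constants$pKa2)
  S0 <- 10^(-constants$pS0)
  K2 <- if (is.finite(constants$logK2)) 10^constants$logK2 else 0
  KH3A2 <- if (is.na(constants$logK_H3A2)) 0 else 10^constants$logK_H3A2
  Ksp <- if (is.na(constants$pKsp_NaHA)) NA else 10^(-constants$pKsp_NaHA)
  Kps <- if (is.na(constants$pKps_NaH3A2)) NA
         else 10^(-constants$pKps_NaH3A2)
  K22 <- if (is.finite(logK22)) 10^logK22 else 0
  supersat <- function(x) {            # x = log10 [H2A]
    h2a <- 10^x
    ha <- Ka1 * h2a / h
    h3a2 <- KH3A2 * h2a * ha
    r <- h2a / S0
    if (!is.na(Ksp)) r <- max(r, Na * ha / Ksp)
    if (!is.na(Kps)) r <- max(r, Na * h3a2 / Kps)
    log10(r)
  }
  x <- uniroot(supersat, c(-30, 2), tol = 1e-13)$root
  h2a <- 10^x
  ha <- Ka1 * h2a / h
  a2 <- Ka2 * ha / h
  h4a2 <- K2 * h2a^2
  h3a2 <- KH3A2 * h2a * ha
  ha2_2 <- K22 * ha^2
  ratios <- c(H2A = h2a / S0,
              NaHA = if (!is.na(Ksp)) Na * ha / Ksp else 0,
              NaH3A2 = if (!is.na(Kps)) Na * h3a2 / Kps else 0)
  list(conc = c(H2A = h2a, HA = ha, A2 = a2, H4A2 = h4a2, H3A2 = h3a2,
                HA2_2 = ha2_2),
       S_T = h2a + ha + a2 + 2 * h4a2 + 2 * h3a2 + 2 * ha2_2,
       controlling = names(ratios)[ratios > 1 - 1e-9])
}

# Random plausible constant sets for property sweeps.
random_constants <- function(n, seed = 42, with_mixed = TRUE) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    mixed <- with_mixed && runif(1) < 0.3
    eq_constants(pKa1 = runif(1, -2, 3), pKa2 = runif(1, 6, 9),
                 pS0 = runif(1, 4, 9), logK2 = runif(1, 5, 12),
                 pKsp_NaHA = runif(1, 2, 6),
                 logK_H3A2 = if (mixed) runif(1, 3, 7) else NA_real_,
                 pKps_NaH3A2 = if (mixed) runif(1, 3, 6) else NA_real_,
                 I_ref = 1.0)
  }))
}

# Finite-difference slope of log10 S_T against pH.
numeric_slope <- function(f, pcH, dp = 1e-4) {
  (f(pcH + dp) - f(pcH - dp)) / (2 * dp)
}
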