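test_that("solve_point matches the direct closed-form total solubility", {
  k <- btb_constants("1.0")
  sp <- solve_point(k, solution_composition(1.0), pcH = 0.60)
  # direct scalar evaluation of the mass balance as an independent check
  direct <- 10^-8.02 + 10^(1.18 - 8.02) / 10^-0.60 +
    10^(1.18 - 7.12 - 8.02) / 10^(-2 * 0.60) + 2 * 10^(9.94 - 2 * 8.02)
  expect_equal(sp$S_T, direct, tolerance = 1e-10)
  expect_identical(sp$controlling_solids, "H2A")
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-9)
  expect_true(all(sp$concentrations >= 0))
})

test_that("mass balance identity holds to 1e-12 without activity corrections", {
  for (k in random_constants(20, seed = 3)) {
    sp <- solve_point(k, solution_composition(0.5), pcH = 2.7)
    cc <- sp$concentrations
    expect_equal(sp$S_T,
                 cc[["H2A"]] + cc[["HA"]] + cc[["A2"]] +
                   2 * cc[["H4A2"]] + 2 * cc[["H3A2"]],
                 tolerance = 1e-12)
    ch <- 10^(-k$pKa1) * cc[["H2A"]] / 10^(-2.7)
    expect_equal(cc[["HA"]], ch, tolerance = 1e-12)
  }
})

test_that("half-ionization: S_T = 2 S0 at pcH = pKa1 with no dimer or salt", {
  k <- eq_constants(pKa1 = 4, pKa2 = 7.12, pS0 = 6)
  sp <- solve_point(k, solution_composition(0.1), pcH = 4)
  expect_equal(sp$S_T, 2 * 10^-6, tolerance = 1e-3)
})

test_that("acid plateau limit: S_T -> S0 + 2 K2 S0^2 well below pKa1", {
  k <- eq_constants(pKa1 = 2, pKa2 = 7.12, pS0 = 6, logK2 = 8)
  sp <- solve_point(k, solution_composition(0.1), pcH = -1)
  expect_equal(sp$S_T, 1e-6 + 2 * 10^(8 - 12), tolerance = 1e-3)
})

test_that("doubling K2 doubles the dimer excess at the acid plateau", {
  k1 <- eq_constants(pKa1 = 6, pKa2 = 7.12, pS0 = 5, logK2 = 7)
  k2 <- eq_constants(pKa1 = 6, pKa2 = 7.12, pS0 = 5, logK2 = 7 + log10(2))
  m <- solution_composition(0.1)
  s1 <- solve_point(k1, m, -1)$S_T - 1e-5
  s2 <- solve_point(k2, m, -1)$S_T - 1e-5
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
})

test_that("solid-phase selection: single candidate, analytic crossover, Model A window", {
  k <- btb_constants("1.0")
  m <- solution_composition(1.0)
  k_only <- eq_constants(pKa1 = k$pKa1, pS0 = k$pS0, logK2 = k$logK2)
  expect_identical(select_solid_phase(k_only, m, 4.5), "H2A")
  # crossover where S0 Ka1/[H+] = Ksp/[Na+], i.e. pcH* = pS0 + pKa1 - pKsp
  cross <- k$pS0 + k$pKa1 - k$pKsp_NaHA - log10(1.0)
  expect_identical(select_solid_phase(k, m, cross - 0.2), "H2A")
  expect_identical(select_solid_phase(k, m, cross + 0.2), "NaHA")
  expect_setequal(select_solid_phase(k, m, cross), c("H2A", "NaHA"))
  # dimer-free strategy in 1.0 M NaCl: salt-of-the-mixed-dimer window
  kA <- btb_constants("1.0", "A")
  regimes <- rle(vapply(seq(0, 5, by = 0.1), function(p)
    paste(select_solid_phase(kA, m, p), collapse = "+"), character(1)))
  expect_identical(regimes$values[!grepl("\\+", regimes$values)],
                   c("H2A", "NaH3A2", "NaHA"))
})

test_that("speciation agrees with the brute-force bisection oracle", {
  sets <- random_constants(100, seed = 11)
  withr::with_seed(12, {
    pcHs <- runif(100, 0, 5.4)
    Nas <- sample(c(0.1, 0.5, 1.0), 100, replace = TRUE)
  })
  for (i in seq_along(sets)) {
    sp <- solve_point(sets[[i]], solution_composition(Nas[i]), pcHs[i])
    or <- oracle_solve(sets[[i]], Nas[i], pcHs[i])
    expect_equal(sp$logS_T, log10(or$S_T), tolerance = 1e-6)
    expect_setequal(sp$controlling_solids, or$controlling)
  }
})

test_that("log S-pH slope discriminates mixed-charge from anion-only dimers", {
  # neutral acid controlling, monoanion-dominated region: slope +1
  k <- eq_constants(pKa1 = 2, pKa2 = 9, pS0 = 6, logK2 = 2)
  slope1 <- numeric_slope(function(p)
    solve_point(k, solution_composition(0.1), p)$logS_T, 5.0)
  expect_equal(slope1, 1, tolerance = 1e-3)
  # mixed-charge dimer H2A.HA- dominating keeps the slope at +1
  km <- eq_constants(pKa1 = 2, pKa2 = 9, pS0 = 4, logK2 = -Inf,
                     logK_H3A2 = 6)
  slope_m <- numeric_slope(function(p)
    solve_point(km, solution_composition(0.1), p)$logS_T, 5.0)
  expect_equal(slope_m, 1, tolerance = 1e-3)
  # a hypothetical (HA-)2 species (oracle only) would give slope +2
  slope2 <- numeric_slope(function(p)
    log10(oracle_solve(k, 0.1, p, logK22 = 6)$S_T), 5.0)
  expect_equal(slope2, 2, tolerance = 1e-3)
})

test_that("half-point back-estimate of pKa1 is plain arithmetic", {
  expect_equal(halfpoint_pKa1_estimate(1.28, 8.03, 10.11), -1.10103,
               tolerance = 1e-6)
  expect_equal(halfpoint_pKa1_estimate(0.60, 8.02, 9.94), -1.62103,
               tolerance = 1e-6)
  expect_equal(halfpoint_pKa1_estimate(0, 8, 8 - log10(2)), 0)
})

test_that("species distribution: normalization, monotone anion rise, crossover band", {
  k <- btb_constants("0.1")
  m <- solution_composition(0.1)
  dist_all <- species_distribution(k, m, seq(0, 5.4, by = 0.2))
  expect_equal(rowSums(dist_all[, c("H2A", "HA", "A2", "H4A2", "H3A2")]),
               rep(1, nrow(dist_all)), tolerance = 1e-9)
  # monotone anion rise for a fixed controlling solid, below the pKa2 region
  grid <- seq(0, 3.4, by = 0.05)
  dist <- species_distribution(k, m, grid, solids = "H2A")
  expect_true(all(diff(dist$HA) > -1e-12))
  # anion/neutral-dimer crossover with ionic-strength corrections enabled
  dist_sr <- species_distribution(k, m, grid,
                                  activity_config("stokes_robinson"))
  ph_half <- attr(dist_sr, "pH_half")
  expect_length(ph_half, 1)
  expect_gt(ph_half, 1.0)
  expect_lt(ph_half, 1.5)
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  k <- btb_constants("0.1")
  expect_error(solve_point(k, solution_composition(0.1), -2),
               "pcH outside")
  expect_error(eq_constants(pKa1 = 8, pKa2 = 7.12, pS0 = 6), "pKa1")
  expect_error(eq_constants(pKa1 = 1, pS0 = 6, pKps_NaH3A2 = 4),
               "requires the mixed dimer")
  expect_error(species_distribution(k, solution_composition(0.1),
                                    c(2, 1)), "sorted")
})
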