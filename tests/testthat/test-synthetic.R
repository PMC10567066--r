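truth_10 <- btb_constants("1.0")

test_that("noiseless generation reproduces the forward model exactly", {
  spec <- generator_spec(truth_10, 1.0, c(0.0, 5.4), n = 15, sigma = 0)
  d <- generate_dataset(spec, seed = 1)
  tr <- attr(d, "truth")
  expect_identical(d$logS, tr$logS_true)
  direct <- logS_T_curve(truth_10, tr$schedule$pcH, tr$schedule$c_NaCl)
  expect_identical(tr$logS_true, direct)
})

test_that("generation is seed-deterministic", {
  spec <- generator_spec(truth_10, 1.0, c(0.0, 5.4), n = 15, sigma = 0.1)
  d1 <- generate_dataset(spec, seed = 17)
  d2 <- generate_dataset(spec, seed = 17)
  d3 <- generate_dataset(spec, seed = 18)
  expect_identical(d1$logS, d2$logS)
  expect_false(identical(d1$logS, d3$logS))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_dataset(spec, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("titrant schedule dilutes the background and respects feasibility", {
  sc <- titrant_schedule(c(0, 2, 4), 1.0, titrant_molarity = 12)
  expect_equal(sc$c_HCl, 10^-c(0, 2, 4))
  expect_true(all(sc$c_NaCl < 1.0) && all(sc$c_NaCl > 0.9))
  # stronger acid needs more titrant, hence more dilution
  expect_true(all(diff(sc$c_NaCl) > 0))
  expect_error(titrant_schedule(-1.2, 1.0, titrant_molarity = 12),
               "unreachable")
})

test_that("the noiseless profile shows an acid plateau then a slope-+1 rise", {
  spec <- generator_spec(truth_10, 1.0, c(0.0, 5.4), n = 40, sigma = 0)
  d <- generate_dataset(spec, seed = 1)
  slopes <- diff(d$logS) / diff(d$pH)
  ph_mid <- (d$pH[-1] + d$pH[-nrow(d)]) / 2
  expect_lt(abs(slopes[1]), 0.15)          # plateau at the acid end
  mid <- which(ph_mid > 2 & ph_mid < 2.45) # monoanion-dominated rise
  expect_true(all(abs(slopes[mid] - 1) < 0.15))
  expect_lt(abs(slopes[length(slopes)]), 0.05)  # salt-limited flat top
})

test_that("noise is calibrated to the requested sigma", {
  spec <- generator_spec(truth_10, 1.0, c(0.5, 5.4), n = 10, sigma = 0.1)
  base <- generate_dataset(generator_spec(truth_10, 1.0, c(0.5, 5.4),
                                          n = 10, sigma = 0), seed = 1)
  res <- vapply(1:1000, function(s)
    generate_dataset(spec, seed = s)$logS - base$logS, numeric(10))
  expect_lt(abs(stats::sd(res) / 0.1 - 1), 0.05)
})

test_that("ground truth round-trips through refinement at sigma = 0", {
  spec <- generator_spec(truth_10, 1.0, c(0.0, 5.4), n = 15, sigma = 0)
  d <- generate_dataset(spec, seed = 1)
  f <- refine(d, truth_10)
  tr <- attr(d, "truth")$constants
  expect_lt(max(abs(f$estimates - c(tr$pS0, tr$logK2, tr$pKsp_NaHA))), 1e-4)
})

test_that("descriptor tables honor the linear model and domain constraints", {
  co <- abraham_coefficients("endo")
  tab <- generate_descriptor_table(50, co, noise = 0, seed = 8)
  pred <- co["a0"] + as.matrix(tab[, c("A", "B", "S", "E", "V")]) %*%
    unname(co[paste0("a", 1:5)])
  expect_equal(tab$ks, as.vector(pred), tolerance = 1e-12)
  expect_true(all(tab$V > 0))
  expect_identical(tab, generate_descriptor_table(50, co, 0, seed = 8))
  expect_error(generate_descriptor_table(4), "n >= 6")
})
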