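truth_01 <- btb_constants("0.1")

test_that("noiseless synthetic data return the generating constants exactly", {
  d <- generate_dataset(generator_spec(truth_01, 0.1, c(0.5, 5.4),
                                       n = 10, sigma = 0), seed = 1)
  f <- refine(d, truth_01)
  expect_lt(max(abs(f$estimates -
                    c(pS0 = 8.03, logK2 = 10.11, pKsp_NaHA = 4.41))), 1e-4)
  expect_lt(f$gof, 1e-6)
  expect_true(f$converged)
})

test_that("estimates are invariant under row permutation and weight scaling", {
  spec <- generator_spec(truth_01, 0.1, c(0.5, 5.4), n = 10, sigma = 0.1)
  d <- generate_dataset(spec, seed = 4)
  f1 <- refine(d, truth_01)
  d_perm <- d[rev(seq_len(nrow(d))), ]
  attr(d_perm, "pH_scale") <- attr(d, "pH_scale")
  class(d_perm) <- class(d)
  f2 <- refine(d_perm, truth_01)
  expect_identical(f1$estimates, f2$estimates)
  # doubling all sigmas: same minimizer, GOF exactly halved
  d2 <- d
  d2$sigma <- 2 * d2$sigma
  f3 <- refine(d2, truth_01)
  expect_equal(f3$estimates, f1$estimates, tolerance = 1e-8)
  expect_equal(f3$gof, f1$gof / 2, tolerance = 1e-8)
})

test_that("one-parameter refinement matches a dense grid search", {
  spec <- generator_spec(truth_01, 0.1, c(0.5, 5.4), n = 10, sigma = 0.1)
  d <- generate_dataset(spec, seed = 9)
  f <- refine(d, truth_01, free = "pS0")
  grid <- seq(7.9, 8.2, by = 1e-4)
  chi2 <- vapply(grid, function(v) {
    kc <- satsol:::update_constants(truth_01, c(pS0 = v))
    sum(((d$logS - logS_T_curve(kc, d$pH, d$c_NaCl)) / d$sigma)^2)
  }, numeric(1))
  expect_lt(abs(unname(f$estimates["pS0"]) - grid[which.min(chi2)]), 1e-4)
})

test_that("Monte-Carlo recovery of the 0.1 M constants stays in band", {
  spec <- generator_spec(truth_01, 0.1, c(0.5, 5.4), n = 10, sigma = 0.1)
  est <- vapply(1:20, function(s)
    refine(generate_dataset(spec, s), truth_01)$estimates, numeric(3))
  means <- rowMeans(est)
  sem <- apply(est, 1, stats::sd) / sqrt(ncol(est))
  truth <- c(pS0 = 8.03, logK2 = 10.11, pKsp_NaHA = 4.41)
  expect_true(all(abs(means - truth) < 3.5 * sem))
})

test_that("jH is recovered when the data reach below pH 2, and degrades without them", {
  k <- btb_constants("1.0")
  spec <- generator_spec(k, 1.0, c(0.0, 5.4), n = 15, sigma = 0.05,
                         jH = 0.3)
  d <- generate_dataset(spec, seed = 2)
  expect_identical(attr(d, "pH_scale"), "operational")
  f <- refine(d, k, free = c("pS0", "logK2", "pKsp_NaHA", "jH"))
  expect_lt(abs(f$jH - 0.3), 3 * f$se[["jH"]])
  # null case: data generated with jH = 0
  d0 <- generate_dataset(generator_spec(k, 1.0, c(0.0, 5.4), n = 15,
                                        sigma = 0.05, jH = 1e-9), seed = 2)
  f0 <- refine(d0, k, free = c("pS0", "logK2", "pKsp_NaHA", "jH"))
  expect_lt(abs(f0$jH), 3 * f0$se[["jH"]])
  # information content: with the other constants at truth, dropping the
  # acidic points inflates se(jH) more than tenfold
  f_j <- refine(d, k, free = "jH")
  keep <- d$pH >= 2
  d_hi <- solubility_dataset(d$pH[keep], d$logS[keep], d$sigma[keep],
                             d$c_NaCl[keep], pH_scale = "operational")
  f_hi <- refine(d_hi, k, free = "jH", hold_jH_without_acid = FALSE)
  expect_gt(f_hi$se[["jH"]], 10 * f_j$se[["jH"]])
  # default policy: jH silently unidentifiable -> held at zero with warning
  expect_warning(f_def <- refine(d_hi, k,
                                 free = c("pS0", "logK2", "pKsp_NaHA",
                                          "jH")),
                 "jH held at 0")
  expect_false("jH" %in% names(f_def$estimates))
})

test_that("block-diagonalization descends and flags the shallow pKa1 well", {
  k <- btb_constants("1.0")
  d <- generate_dataset(generator_spec(k, 1.0, c(0.0, 5.4), n = 15,
                                       sigma = 0.1), seed = 7)
  b <- block_diagonal_refine(d, k)
  expect_true(all(diff(b$cycle_gof) <= 1e-8))
  expect_true("pKa1" %in% names(b$group_B_estimates))
  pr <- gof_profile(d, k, grid = seq(-2, 1, by = 0.5))
  expect_true(attr(pr, "indeterminate"))
  # joint refinement of all four constants must flag its ill-conditioning
  j <- refine(d, k, free = c("pKa1", "pS0", "logK2", "pKsp_NaHA"))
  expect_true(length(j$flags) > 0)
})

test_that("orthogonal parameter groups converge in at most two cycles", {
  # pS0 and pKsp control disjoint pH regions: nearly uncorrelated groups
  k <- btb_constants("0.1")
  d <- generate_dataset(generator_spec(k, 0.1, c(0.5, 5.4), n = 12,
                                       sigma = 0.02), seed = 5)
  b <- block_diagonal_refine(d, k, group_A = c("pS0", "logK2"),
                             group_B = "pKsp_NaHA")
  joint <- refine(d, k, free = c("pS0", "logK2", "pKsp_NaHA"))
  expect_lte(b$cycles, 2)
  # same minimum chi-square as the joint fit (GOF differs only through the
  # degrees-of-freedom normalization of each sub-fit)
  expect_equal(b$chi2, joint$chi2, tolerance = 1e-4)
})

test_that("underdetermined refinements are rejected", {
  d <- generate_dataset(generator_spec(truth_01, 0.1, c(2, 4), n = 4,
                                       sigma = 0.1), seed = 1)
  expect_error(refine(d[1:3, ], truth_01,
                      free = c("pS0", "logK2", "pKsp_NaHA")),
               "at least one more point")
})
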