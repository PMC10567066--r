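#' Refinement control settings
#'
#' @param ftol relative chi-square convergence tolerance.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @param cor_flag absolute parameter correlation above which the result is
#'   flagged for excessive correlation (the regime where joint refinement is
#'   unreliable and block-diagonalization is indicated).
#' @return list of control settings.
#' @export
refine_control <- function(ftol = 1e-10, maxiter = 200, cor_flag = 0.999) {
  list(ftol = ftol, maxiter = maxiter, cor_flag = cor_flag)
}

# Canonical row order: makes estimates invariant (bit-identical) under
# permutation of the input rows despite floating-point summation order.
sort_dataset <- function(dataset) {
  dataset[order(dataset$pH, dataset$c_NaCl, dataset$logS), , drop = FALSE]
}

# Weighted residual vector for a parameter vector p over the free names.
# Operational-scale datasets are standardized to pcH with the current jH.
make_residual_fn <- function(dataset, constants, free, activity, solids,
                             ph_params) {
  operational <- identical(attr(dataset, "pH_scale"), "operational")
  temperature <- attr(dataset, "temperature") %||% 20
  function(p) {
    names(p) <- free
    kc <- update_constants(constants, p[setdiff(free, "jH")])
    pp <- ph_params
    if ("jH" %in% free) pp$jH <- unname(p[["jH"]])
    # a trial jH can push readings off the invertible electrode branch;
    # steer the optimizer back with a large finite residual
    pcH <- if (operational)
      tryCatch(paH_to_pcH(dataset$pH, pp), error = function(e) NULL)
    else dataset$pH
    if (is.null(pcH)) return(rep(1e6, nrow(dataset)))
    calc <- logS_T_curve(kc, pcH, dataset$c_NaCl, activity, solids,
                         temperature)
    (dataset$logS - calc) / dataset$sigma
  }
}

# Central-difference Jacobian of the weighted residuals at the optimum.
num_jacobian <- function(fn, p, rel_step = 1e-6) {
  r0 <- fn(p)
  J <- matrix(0, length(r0), length(p))
  for (j in seq_along(p)) {
    dp <- rel_step * max(1, abs(p[j]))
    up <- p; up[j] <- p[j] + dp
    dn <- p; dn[j] <- p[j] - dp
    J[, j] <- (fn(up) - fn(dn)) / (2 * dp)
  }
  J
}

#' Weighted nonlinear least-squares refinement of equilibrium constants
#'
#' Minimizes \eqn{\chi^2 = \sum_i [(\log S_i^{obs} - \log S_i^{calc})/
#' \sigma_i]^2} over the free constants by Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}), holding the remaining constants fixed.
#' The goodness of fit is \eqn{GOF = \sqrt{\chi^2_{min}/(n-m)}} with m free
#' parameters; standard errors come from the local covariance
#' \eqn{GOF^2 (J^T J)^{-1}} of the weighted Jacobian, and the parameter
#' correlation matrix is reported so that the strongly correlated regime is
#' detectable rather than silently absorbed. Datasets on the operational pH
#' scale are standardized through the electrode map, and \code{"jH"} may be
#' included among the free parameters to refine the acidic junction term
#' alongside the constants (meaningful only when the data contain points
#' below pH 2; without them its standard error blows up).
#'
#' @param dataset a \code{\link{solubility_dataset}}.
#' @param constants starting \code{\link{eq_constants}} (fixed values taken
#'   from here).
#' @param free character vector of free parameter names among
#'   \code{pKa1, pKa2, pS0, logK2, pKsp_NaHA, logK_H3A2, pKps_NaH3A2, jH}.
#' @param activity \code{\link{activity_config}}.
#' @param solids candidate solid set.
#' @param ph_params \code{\link{ph_scale_params}} for operational-scale data.
#' @param control \code{\link{refine_control}}.
#' @param hold_jH_without_acid when \code{TRUE} (default), a free jH is held
#'   at zero with a warning if the dataset has no points below pH 2 (the
#'   junction term carries no information there); set \code{FALSE} to keep
#'   it free anyway, e.g. to examine how its standard error degrades.
#' @return object of class \code{refinement_result}: \code{estimates},
#'   \code{se}, \code{gof}, \code{residuals} (weighted), \code{correlation},
#'   \code{constants} (updated set), \code{n}, \code{m}, \code{converged},
#'   and \code{flags}.
#' @export
refine <- function(dataset, constants, free = c("pS0", "logK2", "pKsp_NaHA"),
                   activity = activity_config(),
                   solids = declared_solids(constants),
                   ph_params = ph_scale_params(),
                   control = refine_control(),
                   hold_jH_without_acid = TRUE) {
  stopifnot(inherits(dataset, "solubility_dataset"), length(free) >= 1)
  n <- nrow(dataset)
  m <- length(free)
  if (n < m + 1)
    stop("dataset must have at least one more point than free parameters")
  if ("jH" %in% free && hold_jH_without_acid &&
      identical(attr(dataset, "pH_scale"), "operational") &&
      !any(dataset$pH < 2)) {
    warning("no points below pH 2: jH held at 0")
    free <- setdiff(free, "jH")
    m <- length(free)
  }
  dataset <- sort_dataset(dataset)
  fn <- make_residual_fn(dataset, constants, free, activity, solids,
                         ph_params)
  start <- vapply(free, function(f)
    if (f == "jH") ph_params$jH else constants[[f]], numeric(1))
  fit <- minpack.lm::nls.lm(
    par = start, fn = fn,
    control = minpack.lm::nls.lm.control(ftol = control$ftol,
                                         maxiter = control$maxiter))
  est <- fit$par
  names(est) <- free
  r <- fn(est)
  chi2 <- sum(r^2)
  gof <- sqrt(chi2 / (n - m))
  J <- num_jacobian(fn, est)
  JtJ <- crossprod(J)
  flags <- character(0)
  # unscaled covariance shape: correlations are scale-free, so a perfect
  # fit (GOF = 0) still yields a meaningful correlation matrix
  V <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(V)) {
    flags <- c(flags, "singular_normal_equations")
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    V <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  se <- gof * sqrt(pmax(diag(V), 0))
  names(se) <- free
  cor_mat <- suppressWarnings(stats::cov2cor(V))
  dimnames(cor_mat) <- list(free, free)
  off <- abs(cor_mat[upper.tri(cor_mat)])
  off <- off[is.finite(off)]
  if (length(off) && any(off > control$cor_flag))
    flags <- c(flags, "excessive_correlation")
  structure(list(estimates = est, se = se, gof = gof, chi2 = chi2,
                 residuals = r, correlation = cor_mat,
                 constants = update_constants(constants,
                                              est[setdiff(free, "jH")]),
                 jH = if ("jH" %in% free) unname(est[["jH"]]) else NULL,
                 n = n, m = m,
                 converged = fit$info %in% 1:4, info = fit$message,
                 flags = flags),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("Refinement: %d points, %d free parameter(s), GOF = %.3f\n",
              x$n, x$m, x$gof))
  for (f in names(x$estimates))
    cat(sprintf("  %-12s %9.4f +/- %.4f\n", f, x$estimates[[f]], x$se[[f]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Block-diagonalization refinement of strongly correlated groups
#'
#' Alternates weighted least-squares refinement of two disjoint parameter
#' groups (each refined with the other held fixed) until the goodness of fit
#' stops improving, the scheme used when extreme correlation between an
#' ionization constant and the solubility/aggregation constants defeats
#' joint refinement. Records the GOF trajectory per accepted cycle; an
#' oscillating trajectory (no decrease between cycles) terminates the loop
#' with a flag rather than silently.
#'
#' @param dataset a \code{\link{solubility_dataset}}.
#' @param constants starting \code{\link{eq_constants}}.
#' @param group_A first parameter group (e.g. \code{c("pS0", "logK2",
#'   "pKsp_NaHA")}).
#' @param group_B second group (e.g. \code{"pKa1"}).
#' @param activity,solids,ph_params,control as in \code{\link{refine}}.
#' @param max_cycles maximum A/B alternation cycles.
#' @param tol stop when the GOF improves by less than this between cycles.
#' @return a \code{refinement_result} for the final state, with extra fields
#'   \code{cycle_gof} (trajectory) and \code{cycles}.
#' @export
block_diagonal_refine <- function(dataset, constants,
                                  group_A = c("pS0", "logK2", "pKsp_NaHA"),
                                  group_B = "pKa1",
                                  activity = activity_config(),
                                  solids = declared_solids(constants),
                                  ph_params = ph_scale_params(),
                                  control = refine_control(),
                                  max_cycles = 20, tol = 1e-6) {
  if (length(intersect(group_A, group_B)))
    stop("parameter groups must be disjoint")
  traj <- numeric(0)
  fitA <- NULL
  gof_prev <- Inf
  for (cyc in seq_len(max_cycles)) {
    fitA <- refine(dataset, constants, group_A, activity, solids, ph_params,
                   control)
    constants <- fitA$constants
    fitB <- refine(dataset, constants, group_B, activity, solids, ph_params,
                   control)
    constants <- fitB$constants
    traj <- c(traj, fitB$gof)
    if (gof_prev - fitB$gof < tol) break
    gof_prev <- fitB$gof
  }
  # final pass over group A at the settled group B values
  out <- refine(dataset, constants, group_A, activity, solids, ph_params,
                control)
  out$group_B_estimates <- fitB$estimates
  out$group_B_se <- fitB$se
  out$cycle_gof <- traj
  out$cycles <- length(traj)
  if (length(traj) > 1 && any(diff(traj) > tol))
    out$flags <- c(out$flags, "oscillation")
  out
}

#' Goodness-of-fit profile over one fixed parameter
#'
#' Scans a grid of fixed values of one constant (typically pKa1), refining
#' the remaining free constants at each grid point, and reports the attained
#' GOF. A flat profile (max - min below \code{flat_frac} of the mean level)
#' is flagged \code{indeterminate}: the data cannot pin the scanned constant
#' down, the shallow-well behavior characteristic of saturation solubility
#' data for this system.
#'
#' @param dataset a \code{\link{solubility_dataset}}.
#' @param constants \code{\link{eq_constants}}.
#' @param param the scanned constant name.
#' @param grid numeric vector of fixed values for \code{param}.
#' @param free constants refined at each grid point.
#' @param activity,solids,ph_params,control as in \code{\link{refine}}.
#' @param flat_frac flatness threshold as a fraction of the mean GOF.
#' @return data.frame \code{(value, gof)} with attributes
#'   \code{"indeterminate"} (logical) and \code{"flat_fraction"}.
#' @export
gof_profile <- function(dataset, constants, param = "pKa1",
                        grid = seq(-2, 1, by = 0.25),
                        free = c("pS0", "logK2", "pKsp_NaHA"),
                        activity = activity_config(),
                        solids = declared_solids(constants),
                        ph_params = ph_scale_params(),
                        control = refine_control(), flat_frac = 0.1) {
  gofs <- vapply(grid, function(v) {
    kc <- update_constants(constants, stats::setNames(v, param))
    refine(dataset, kc, free, activity, solids, ph_params, control)$gof
  }, numeric(1))
  out <- data.frame(value = grid, gof = gofs)
  span <- (max(gofs) - min(gofs)) / mean(gofs)
  attr(out, "flat_fraction") <- span
  attr(out, "indeterminate") <- span < flat_frac
  out
}
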