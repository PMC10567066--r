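#' Setschenow line fit
#'
#' Least-squares line \code{p_value = intercept + slope * Cs} through
#' (salt concentration, -log10 solubility/constant) points; with two points
#' the line is exact. A positive slope of a pS-type quantity against salt is
#' salting-out.
#'
#' @param Cs salt concentrations (M), at least two distinct values.
#' @param p_value the -log10 quantity at each salt level (e.g. apparent pS0
#'   or pS_T).
#' @return object of class \code{salting_fit}: \code{intercept} (zero-salt
#'   value), \code{slope} (M^-1), \code{points}, \code{residuals}.
#' @examples
#' fit_setschenow(c(0, 1.0), c(5.10, 5.878))  # slope 0.778
#' @export
fit_setschenow <- function(Cs, p_value) {
  stopifnot(length(Cs) == length(p_value), length(Cs) >= 2)
  if (length(unique(Cs)) < 2)
    stop("need at least two distinct salt concentrations")
  fit <- stats::lm(p_value ~ Cs)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 points = data.frame(Cs = Cs, p_value = p_value),
                 residuals = unname(stats::residuals(fit))),
            class = "salting_fit")
}

#' @export
print.salting_fit <- function(x, ...) {
  cat(sprintf("Setschenow fit: p = %.4f %+.4f * Cs (n = %d)\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}

#' True salting-out parameter from apparent intrinsic solubilities
#'
#' The slope of apparent pS0 (refined per medium with neutral-species
#' salting disabled) against the medium's salt concentration is the true
#' salting-out parameter ks of the neutral monomer, free of the
#' self-association contamination that inflates the empirical
#' total-solubility Setschenow constant.
#'
#' @param Cs salt concentrations (M).
#' @param pS0_app apparent (per-medium) refined pS0 values.
#' @return a \code{\link{fit_setschenow}} result; the \code{slope} is ks
#'   (M^-1) and the \code{intercept} the zero-salt pS0.
#' @export
derive_true_salting <- function(Cs, pS0_app) {
  fit_setschenow(Cs, pS0_app)
}

#' Abraham linear free-energy prediction of a salting-out constant
#'
#' Evaluates \code{ks = a0 + a1*A + a2*B + a3*S + a4*E + a5*V} for a solute
#' with Abraham descriptors (H-bond acidity A, basicity B,
#' dipolarity/polarizability S, excess molar refractivity E, McGowan volume
#' V), returning the prediction and the additive per-term contributions.
#' Large molecules (V) push toward stronger salting-out; polar terms act in
#' the opposite direction.
#'
#' @param descriptors named numeric vector with entries \code{A, B, S, E, V}
#'   (see \code{\link{btb_descriptors}}).
#' @param coefficients named vector \code{a0..a5} (see
#'   \code{\link{abraham_coefficients}}).
#' @return list with \code{ks} (M^-1) and \code{contributions} (named,
#'   including the intercept).
#' @examples
#' abraham_predict(btb_descriptors(), abraham_coefficients("endo"))$ks
#' @export
abraham_predict <- function(descriptors,
                            coefficients = abraham_coefficients("endo")) {
  need <- c("A", "B", "S", "E", "V")
  if (!all(need %in% names(descriptors)) ||
      any(!is.finite(descriptors[need])))
    stop("all five descriptors A, B, S, E, V are required")
  contrib <- c(a0 = unname(coefficients["a0"]),
               stats::setNames(unname(coefficients[paste0("a", 1:5)]) *
                               unname(descriptors[need]), need))
  list(ks = sum(contrib), contributions = contrib)
}

#' Fit Abraham salting coefficients by partial least squares
#'
#' Regresses observed salting-out constants on the five Abraham descriptors
#' by PLS (\code{mixOmics::pls}, regression mode), choosing the number of
#' latent components by k-fold cross-validation on root-mean-square
#' prediction error. With the full five components the fit coincides with
#' ordinary least squares, so a noiseless linear table is recovered exactly.
#' Coefficients on the original descriptor scale are extracted from the
#' fitted linear predictor.
#'
#' @param table data.frame with columns \code{A, B, S, E, V, ks}.
#' @param ncomp number of components, or \code{"cv"} to select by
#'   cross-validation.
#' @param folds number of CV folds.
#' @param seed seed for the CV fold assignment.
#' @return list with \code{coefficients} (named \code{a0..a5}),
#'   \code{ncomp}, and \code{cv_rmsep} (per candidate component count, when
#'   CV was used).
#' @export
pls_fit_coefficients <- function(table, ncomp = "cv", folds = 5, seed = 1) {
  need <- c("A", "B", "S", "E", "V", "ks")
  if (!all(need %in% names(table)))
    stop("training table must have columns A, B, S, E, V, ks")
  table <- table[, need]
  if (nrow(table) < 6) stop("need at least 6 training rows")
  if (!requireNamespace("mixOmics", quietly = TRUE))
    stop("pls_fit_coefficients requires the mixOmics package")
  X <- as.matrix(table[, c("A", "B", "S", "E", "V")])
  y <- table$ks
  if (qr(scale(X, scale = FALSE))$rank < ncol(X))
    stop("rank-deficient descriptor design")
  fit_one <- function(Xtr, ytr, nc)
    mixOmics::pls(Xtr, ytr, ncomp = nc, mode = "regression", scale = FALSE)
  pred <- function(fit, Xnew, nc) {
    colnames(Xnew) <- colnames(X)
    predict(fit, Xnew)$predict[, 1, nc]
  }
  cv_rmsep <- NULL
  if (identical(ncomp, "cv")) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    fold <- sample(rep_len(seq_len(folds), nrow(X)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cv_rmsep <- vapply(1:5, function(nc) {
      se <- unlist(lapply(seq_len(folds), function(k) {
        tr <- fold != k
        f <- fit_one(X[tr, , drop = FALSE], y[tr], nc)
        (y[!tr] - pred(f, X[!tr, , drop = FALSE], nc))^2
      }))
      sqrt(mean(se))
    }, numeric(1))
    ncomp <- which.min(cv_rmsep)
  }
  fit <- fit_one(X, y, ncomp)
  # the PLS predictor is linear; read the coefficients off the basis vectors
  a0 <- pred(fit, matrix(0, 1, 5), ncomp)
  a <- vapply(1:5, function(j) {
    e <- matrix(0, 1, 5); e[1, j] <- 1
    pred(fit, e, ncomp) - a0
  }, numeric(1))
  list(coefficients = stats::setNames(c(a0, a), paste0("a", 0:5)),
       ncomp = ncomp, cv_rmsep = cv_rmsep)
}
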