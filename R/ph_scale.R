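#' Electrode standardization parameters
#'
#' Parameters of the four-parameter map between the operational pH reading
#' (paH) and the hydrogen-ion concentration scale (pcH):
#' \deqn{paH = \alpha + k \cdot pcH + j_H [H^+] + j_{OH} [OH^-]}
#' with \eqn{[H^+] = 10^{-pcH}} and \eqn{[OH^-] = K_w 10^{pcH}}. The jH term
#' absorbs liquid-junction and electrode asymmetry effects in strongly acidic
#' solutions (pH < 2); jOH is its alkaline counterpart. An electrode
#' calibrated directly on the concentration scale corresponds to
#' \code{alpha = jOH = 0, k = 1}, leaving only the jH correction.
#'
#' @param alpha intercept offset.
#' @param k electrode slope factor.
#' @param jH acidic junction/asymmetry coefficient (M^-1).
#' @param jOH alkaline junction coefficient (M^-1).
#' @param pKw -log10 of the water ionization constant (14.17 at 20 C).
#' @return object of class \code{ph_scale_params}.
#' @export
ph_scale_params <- function(alpha = 0, k = 1, jH = 0, jOH = 0, pKw = 14.17) {
  stopifnot(is.finite(alpha), is.finite(k), is.finite(jH), is.finite(jOH))
  structure(list(alpha = alpha, k = k, jH = jH, jOH = jOH, pKw = pKw),
            class = "ph_scale_params")
}

#' Forward electrode map: concentration scale to operational reading
#'
#' @param pcH hydrogen-ion concentration exponent(s), -log10 [H+].
#' @param params \code{\link{ph_scale_params}}.
#' @return operational pH reading(s) paH.
#' @export
pcH_to_paH <- function(pcH, params = ph_scale_params()) {
  h <- 10^(-pcH)
  oh <- 10^(-params$pKw) / h
  params$alpha + params$k * pcH + params$jH * h + params$jOH * oh
}

#' Invert the electrode map: operational reading to concentration scale
#'
#' Numerically inverts the four-parameter electrode equation. A positive jH
#' makes the map non-monotone far below pH 0 (the junction term eventually
#' dominates), so the inversion works on the physically relevant monotone
#' branch that extends to high pH; readings that fall off that branch, i.e.
#' a parameterization that cannot explain them monotonically, are rejected.
#'
#' @param paH operational pH reading(s).
#' @param params \code{\link{ph_scale_params}}.
#' @param interval pcH search interval.
#' @return pcH value(s); round-trips with \code{\link{pcH_to_paH}} to 1e-10
#'   on the monotone branch.
#' @export
paH_to_pcH <- function(paH, params = ph_scale_params(),
                       interval = c(-1.5, 9)) {
  grid <- seq(interval[1], interval[2], length.out = 1000)
  fw <- pcH_to_paH(grid, params)
  d <- diff(fw)
  lo <- interval[1]
  if (any(d <= 0)) {
    i0 <- max(which(d <= 0)) + 1
    if (i0 >= length(grid))
      stop("electrode map is not monotone over the operating range; ",
           "rejecting the parameterization")
    lo <- grid[i0]
  }
  lo_val <- pcH_to_paH(lo, params)
  if (any(paH < lo_val))
    stop("electrode map is not monotone over the operating range; ",
         "reading(s) below the invertible branch (paH < ",
         format(lo_val, digits = 4), ")")
  vapply(paH, function(y) {
    stats::uniroot(function(x) pcH_to_paH(x, params) - y,
                   interval = c(lo, interval[2]), tol = 1e-12,
                   extendInt = "upX")$root
  }, numeric(1))
}
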