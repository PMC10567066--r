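#' Model strategy fixtures
#'
#' The three analysis strategies for the bromothymol blue saturation data,
#' shipped as immutable fixtures:
#' \describe{
#'   \item{A}{dimer-free alternative: pKa1 fixed at 1.43 (I_ref = 0.1 M),
#'     free pS0 and pKsp in 0.1 M NaCl; in 1.0 M NaCl the mixed-charge dimer
#'     H2A.HA- and the second salt solid NaH3A2(s) are invoked (pS0 fixed at
#'     its 0.1 M value), with free logK_H3A2, pKps and pKsp. Depends on an
#'     unusually large empirical salting constant (0.778 M^-1).}
#'   \item{B}{neutral-dimer model with pKa1 sought from the solubility data
#'     itself by block-diagonalization (alternating refinement of
#'     \{pS0, logK2, pKsp\} and \{pKa1\}), plus a GOF profile scan that
#'     flags the shallow-well indeterminacy of pKa1.}
#'   \item{C}{neutral-dimer model with pKa1 fixed at the independently
#'     measured value re-referenced to the 1.0 M CIM scale (-1.18); free
#'     pS0, logK2, pKsp per medium, followed by the cross-medium salting
#'     analysis (apparent pS0 vs Cs).}
#' }
#'
#' @param name \code{"A"}, \code{"B"} or \code{"C"}.
#' @return object of class \code{model_strategy}.
#' @export
model_strategy <- function(name = c("C", "A", "B")) {
  name <- match.arg(name)
  plan <- switch(name,
    C = list(
      "0.1" = list(constants = btb_constants("0.1", "C"),
                   free = c("pS0", "logK2", "pKsp_NaHA")),
      "1.0" = list(constants = btb_constants("1.0", "C"),
                   free = c("pS0", "logK2", "pKsp_NaHA"))),
    A = list(
      "0.1" = list(constants = btb_constants("0.1", "A"),
                   free = c("pS0", "pKsp_NaHA")),
      "1.0" = list(constants = btb_constants("1.0", "A"),
                   free = c("logK_H3A2", "pKps_NaH3A2", "pKsp_NaHA"))),
    B = list(
      "0.1" = list(constants = btb_constants("0.1", "C"),
                   free = c("pS0", "logK2", "pKsp_NaHA"), block = TRUE),
      "1.0" = list(constants = btb_constants("1.0", "C"),
                   free = c("pS0", "logK2", "pKsp_NaHA"), block = TRUE)))
  structure(list(name = name, plan = plan,
                 provenance = switch(name,
                   A = "pKa1 = 1.43 refined from the 0.1 M data themselves",
                   B = "pKa1 sought by block-diagonalization; indeterminate",
                   C = paste("pKa1 = -0.66 at I = 4.59 M, re-referenced to",
                             "1.0 M by the Stokes-Robinson correction"))),
            class = "model_strategy")
}

#' Run one model strategy over per-medium datasets
#'
#' Executes the strategy's fixed/free refinement plan on each medium's
#' dataset, then the strategy-specific follow-up: the cross-medium salting
#' analysis (apparent pS0 against salt level) for model C, and the pKa1
#' GOF-profile indeterminacy scan for model B. The report records every
#' fixed constant, activity setting and tolerance used.
#'
#' @param strategy a \code{\link{model_strategy}}.
#' @param datasets named list of \code{\link{solubility_dataset}} objects;
#'   names are medium labels matching the strategy plan (\code{"0.1"},
#'   \code{"1.0"}).
#' @param activity \code{\link{activity_config}} used in refinement.
#' @param control \code{\link{refine_control}}.
#' @param profile_grid pKa1 grid for the model-B indeterminacy scan.
#' @return object of class \code{satsol_report}.
#' @export
run_strategy <- function(strategy, datasets,
                         activity = activity_config(),
                         control = refine_control(),
                         profile_grid = seq(-2, 1, by = 0.25)) {
  stopifnot(inherits(strategy, "model_strategy"))
  if (!length(datasets) || is.null(names(datasets)))
    stop("datasets must be a non-empty named list (media labels)")
  media <- names(datasets)
  unknown <- setdiff(media, names(strategy$plan))
  if (length(unknown))
    stop("strategy ", strategy$name, " has no plan for media: ",
         paste(unknown, collapse = ", "))
  for (m in media) {
    d <- datasets[[m]]
    if (!inherits(d, "solubility_dataset") || nrow(d) == 0)
      stop("empty or invalid dataset for medium ", m)
  }
  media <- sort(media)
  fits <- list()
  profiles <- list()
  for (m in media) {
    p <- strategy$plan[[m]]
    fits[[m]] <- if (isTRUE(p$block))
      block_diagonal_refine(datasets[[m]], p$constants,
                            group_A = p$free, group_B = "pKa1",
                            activity = activity, control = control)
    else
      refine(datasets[[m]], p$constants, p$free, activity = activity,
             control = control)
    if (strategy$name == "B")
      profiles[[m]] <- gof_profile(datasets[[m]], p$constants,
                                   grid = profile_grid, free = p$free,
                                   activity = activity, control = control)
  }
  salting <- NULL
  if (strategy$name == "C" && length(media) >= 2) {
    Cs <- as.numeric(media)
    pS0_app <- vapply(media, function(m)
      unname(fits[[m]]$estimates["pS0"]), numeric(1))
    salting <- derive_true_salting(Cs, pS0_app)
  }
  log <- c(sprintf("strategy %s: %s", strategy$name, strategy$provenance),
           sprintf("activity: charged=%s neutral=%s ks=%g ks_dimer=%g",
                   activity$charged, activity$neutral, activity$ks,
                   activity$ks_dimer),
           sprintf("refine control: ftol=%g maxiter=%d", control$ftol,
                   control$maxiter),
           vapply(media, function(m)
             sprintf("medium %s: n=%d fixed={%s} label='%s'", m,
                     nrow(datasets[[m]]),
                     paste(setdiff(c("pKa1", "pKa2", "pS0", "logK2",
                                     "pKsp_NaHA"),
                                   strategy$plan[[m]]$free),
                           collapse = ","),
                     attr(datasets[[m]], "label")), character(1)))
  structure(list(strategy = strategy$name, media = media, fits = fits,
                 salting = salting, profiles = profiles,
                 data = lapply(datasets[media], as.data.frame),
                 log = unname(log)),
            class = "satsol_report")
}

#' @export
print.satsol_report <- function(x, ...) {
  cat("== Strategy", x$strategy, "==\n")
  for (m in x$media) {
    cat("-- medium", m, "M NaCl --\n")
    print(x$fits[[m]])
    if (!is.null(x$profiles[[m]]))
      cat(sprintf("  pKa1 profile: GOF span %.1f%% of level -> %s\n",
                  100 * attr(x$profiles[[m]], "flat_fraction"),
                  if (attr(x$profiles[[m]], "indeterminate"))
                    "indeterminate" else "determinate"))
  }
  if (!is.null(x$salting))
    cat(sprintf("Salting analysis: pS0 = %.3f %+.3f * Cs (ks = %.3f M^-1)\n",
                x$salting$intercept, x$salting$slope, x$salting$slope))
  invisible(x)
}

#' Compare strategy reports side by side
#'
#' Tabulates constants, goodness of fit and qualitative flags of two or more
#' strategy reports run on identical datasets, ordered deterministically by
#' strategy name and medium.
#'
#' @param reports list of \code{\link{run_strategy}} reports.
#' @return data.frame with one row per (strategy, medium).
#' @export
compare_strategies <- function(reports) {
  stopifnot(length(reports) >= 2)
  ref <- reports[[1]]$data
  for (r in reports[-1])
    if (!identical(r$data, ref))
      stop("reports were not produced on identical datasets")
  rows <- do.call(rbind, lapply(reports, function(r) {
    do.call(rbind, lapply(r$media, function(m) {
      f <- r$fits[[m]]
      est <- function(nm) if (nm %in% names(f$estimates))
        unname(f$estimates[nm]) else unname(f$constants[[nm]]) %||% NA_real_
      flg <- f$flags
      if (!is.null(r$profiles[[m]]) &&
          attr(r$profiles[[m]], "indeterminate"))
        flg <- c(flg, "indeterminate_pKa1")
      data.frame(strategy = r$strategy, medium = m, gof = f$gof,
                 pKa1 = est("pKa1"), pS0 = est("pS0"), logK2 = est("logK2"),
                 pKsp_NaHA = est("pKsp_NaHA"),
                 flags = paste(flg, collapse = ";"))
    }))
  }))
  rows <- rows[order(rows$strategy, rows$medium), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
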