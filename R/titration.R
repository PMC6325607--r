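# Cysteine pKa determination from pH-activity titration and free-thiol
# quantification (Ellman's assay).

#' Cysteine pKa from an iodoacetamide protection titration
#'
#' Residual activity after alkylation reflects the thiol/thiolate
#' equilibrium of the reactive cysteine: only the thiolate is alkylated,
#' so activity falls sigmoidally with pH. The single-site model
#' \deqn{R(pH) = bottom + (top - bottom) / (1 + 10^{pH - pKa})}
#' (a rearranged Henderson-Hasselbalch relation with Hill coefficient 1)
#' is fitted by nonlinear least squares. The top plateau is fixed at 100%
#' by default (activity is expressed relative to the untreated maximum);
#' pass `top = NULL` to fit it.
#'
#' @param pH Numeric vector of pH values.
#' @param activity_pct Residual activities (% of maximal, untreated).
#' @param top Fixed top plateau (default 100); NULL to estimate.
#' @param bottom_start Start value for the bottom plateau.
#' @return List of class `pka_fit` with `pKa`, `pKa_se`, `top`, `bottom`,
#'   `bottom_se` and `fitted` (function of pH).
#' @export
fit_pka <- function(pH, activity_pct, top = 100, bottom_start = 0) {
  stopifnot(length(pH) == length(activity_pct))
  if (length(pH) < 5L) stop("need at least 5 titration points")
  if (any(pH < 0 | pH > 14)) stop("pH values must lie in [0, 14]")
  if (any(activity_pct < 0)) stop("activities must be >= 0")
  dat <- data.frame(pH = pH, R = activity_pct)
  span <- diff(range(activity_pct))
  if (span < 1e-6) stop("no transition in the sampled pH range")
  # start pKa: pH nearest the half-amplitude crossing
  half <- (max(activity_pct) + min(activity_pct)) / 2
  pka0 <- pH[which.min(abs(activity_pct - half))]
  if (is.null(top)) {
    nf <- stats::nls(R ~ bottom + (top - bottom) / (1 + 10^(pH - pKa)),
                     data = dat,
                     start = list(top = max(activity_pct),
                                  bottom = bottom_start, pKa = pka0),
                     control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                                  warnOnly = TRUE))
    cf <- summary(nf)$coefficients
    top_est <- cf["top", "Estimate"]
  } else {
    top_fixed <- top
    nf <- stats::nls(R ~ bottom + (top_fixed - bottom) / (1 + 10^(pH - pKa)),
                     data = dat,
                     start = list(bottom = bottom_start, pKa = pka0),
                     control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                                  warnOnly = TRUE))
    cf <- summary(nf)$coefficients
    top_est <- top
  }
  pKa <- cf["pKa", "Estimate"]
  bottom <- cf["bottom", "Estimate"]
  if (pKa < min(pH) || pKa > max(pH)) {
    warning("fitted pKa lies outside the sampled pH range")
  }
  if (top_est <= bottom) warning("fitted top plateau does not exceed bottom")
  out <- list(pKa = pKa, pKa_se = cf["pKa", "Std. Error"],
              top = top_est, bottom = bottom,
              bottom_se = cf["bottom", "Std. Error"],
              fitted = function(x) bottom + (top_est - bottom) /
                (1 + 10^(x - pKa)))
  class(out) <- "pka_fit"
  out
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit> pKa = %.3f +/- %.3f (top %.1f, bottom %.1f)\n",
              x$pKa, x$pKa_se, x$top, x$bottom))
  invisible(x)
}

#' Free thiols per subunit from DTNB absorbance
#'
#' Beer-Lambert conversion of the released TNB chromophore absorbance at
#' 412 nm into thiol equivalents per protein subunit.
#'
#' @param A412 Absorbance at 412 nm (>= 0).
#' @param subunit_conc_M Protein subunit concentration (mol/L, > 0).
#' @param epsilon412 TNB molar absorptivity (default 14150 1/(M cm)).
#' @param path_cm Path length in cm (default 1).
#' @return Thiols per subunit.
#' @examples
#' thiols_per_subunit(0.0985, 6.0e-6)  # ~1.16
#' @export
thiols_per_subunit <- function(A412, subunit_conc_M, epsilon412 = 14150,
                               path_cm = 1) {
  if (any(A412 < 0)) stop("absorbance must be >= 0")
  if (any(subunit_conc_M <= 0)) stop("subunit concentration must be > 0")
  A412 / (epsilon412 * path_cm * subunit_conc_M)
}

#' Read a titration CSV
#'
#' @param path CSV with columns `pH`, `activity_pct`.
#' @return data.frame of titration points.
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("titration CSV not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("pH", "activity_pct"), names(d))
  if (length(miss) > 0L) {
    stop(sprintf("titration CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  d
}
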