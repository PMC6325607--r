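# Enzyme activity computation, inactivation/reactivation kinetics and
# Michaelis-Menten fitting.

#' Enzyme units and specific activity from an absorbance slope
#'
#' Converts an initial NADH formation rate (delta A340 per minute) into
#' enzyme units (1 U = 1 umol NAD+ reduced per minute) via Beer-Lambert,
#' and into specific activity when the enzyme mass is supplied.
#'
#' @param slope Initial slope, delta A340 per minute (>= 0).
#' @param volume_L Assay volume in litres.
#' @param path_cm Optical path length in cm.
#' @param epsilon340 NADH molar absorptivity at 340 nm (default 6220
#'   1/(M cm)).
#' @param enzyme_mg Enzyme mass in the assay (mg); optional.
#' @return List with `units` (U) and `specific_activity` (U/mg, NA when
#'   `enzyme_mg` is missing).
#' @examples
#' activity_from_absorbance(0.6220, volume_L = 1e-3)$units  # 0.1 U
#' @export
activity_from_absorbance <- function(slope, volume_L, path_cm = 1,
                                     epsilon340 = 6220, enzyme_mg = NULL) {
  if (slope < 0) stop("slope must be >= 0")
  if (volume_L <= 0) stop("assay volume must be > 0")
  # slope/(eps*path) = mol/L/min; * volume = mol/min; * 1e6 = umol/min = U
  units <- slope / (epsilon340 * path_cm) * volume_L * 1e6
  sa <- NA_real_
  if (!is.null(enzyme_mg)) {
    if (enzyme_mg <= 0) stop("enzyme mass must be > 0 for specific activity")
    sa <- units / enzyme_mg
  }
  list(units = units, specific_activity = sa)
}

#' Pseudo-first-order inactivation fit
#'
#' Fits a single-exponential decay A(t) = A0 * exp(-k_obs * t) to a
#' relative-activity time course by nonlinear least squares on the linear
#' scale (avoiding the heteroscedastic bias of log-linear regression;
#' `log_linear = TRUE` switches to regression of log A on t). The
#' half-time is reported both from the model (ln 2 / k_obs) and by direct
#' linear interpolation of the 50% crossing.
#'
#' @param time_s Numeric vector of times (s), strictly increasing.
#' @param activity_pct Relative activities (% of initial), >= 0.
#' @param log_linear Use log-linear regression instead of nls.
#' @return List of class `inactivation_fit` with `k_obs` (1/s), `se`,
#'   `A0`, `t_half` (= ln 2 / k_obs), `t_half_interpolated` (s, NA when
#'   the course never crosses 50%).
#' @export
fit_inactivation <- function(time_s, activity_pct, log_linear = FALSE) {
  stopifnot(length(time_s) == length(activity_pct))
  if (length(time_s) < 3L) stop("need at least 3 time points")
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(activity_pct < 0)) stop("activities must be >= 0")
  dat <- data.frame(t = time_s, A = activity_pct)
  if (all(diff(activity_pct) >= 0)) {
    warning("activity does not decrease; returning k_obs = 0")
    fit <- list(k_obs = 0, se = NA_real_, A0 = activity_pct[1],
                t_half = Inf, t_half_interpolated = NA_real_)
    class(fit) <- "inactivation_fit"
    return(fit)
  }
  # log-linear start values (guard zero activities)
  pos <- dat$A > 0
  lf <- stats::lm(log(A) ~ t, data = dat[pos, , drop = FALSE])
  k0 <- max(-stats::coef(lf)[["t"]], 1e-8)
  A00 <- exp(stats::coef(lf)[["(Intercept)"]])
  if (log_linear) {
    k <- k0
    se <- summary(lf)$coefficients["t", "Std. Error"]
    A0 <- A00
  } else {
    nf <- stats::nls(A ~ A0 * exp(-k * t), data = dat,
                     start = list(A0 = A00, k = k0),
                     control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                                  warnOnly = TRUE))
    cf <- summary(nf)$coefficients
    k <- cf["k", "Estimate"]
    se <- cf["k", "Std. Error"]
    A0 <- cf["A0", "Estimate"]
  }
  fit <- list(k_obs = k, se = se, A0 = A0,
              t_half = log(2) / k,
              t_half_interpolated = .interp_half_time(time_s, activity_pct,
                                                      A0 = activity_pct[1]))
  class(fit) <- "inactivation_fit"
  fit
}

# first linear-interpolated crossing of 50% of the initial activity
.interp_half_time <- function(time_s, activity_pct, A0) {
  target <- A0 / 2
  below <- which(activity_pct <= target)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1]
  if (j == 1L) return(time_s[1])
  t1 <- time_s[j - 1L]; t2 <- time_s[j]
  a1 <- activity_pct[j - 1L]; a2 <- activity_pct[j]
  if (a1 == a2) return(t2)
  t1 + (a1 - target) / (a1 - a2) * (t2 - t1)
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("<inactivation_fit> k_obs = %.4g 1/s (t1/2 = %.4g s)\n",
              x$k_obs, x$t_half))
  invisible(x)
}

#' Apparent second-order rate constant
#'
#' Origin-forced least-squares slope of the pseudo-first-order rate
#' constant against reagent concentration, k_obs = k2 * C. An optional
#' intercept accommodates spontaneous inactivation.
#'
#' @param conc_M Reagent concentrations (mol/L).
#' @param k_obs Fitted pseudo-first-order rate constants (1/s).
#' @param intercept Include an intercept term (default FALSE: buffer-only
#'   controls show no spontaneous loss).
#' @return List of class `second_order_fit` with `k2` (1/(M s)) and `se`.
#' @export
fit_second_order <- function(conc_M, k_obs, intercept = FALSE) {
  stopifnot(length(conc_M) == length(k_obs))
  if (length(conc_M) < 2L) stop("need at least 2 concentrations")
  if (all(conc_M == 0)) stop("all concentrations are zero")
  fm <- if (intercept) k_obs ~ conc_M else k_obs ~ conc_M - 1
  lf <- stats::lm(fm)
  cf <- summary(lf)$coefficients
  out <- list(k2 = cf["conc_M", "Estimate"], se = cf["conc_M", "Std. Error"])
  class(out) <- "second_order_fit"
  out
}

#' @export
print.second_order_fit <- function(x, ...) {
  cat(sprintf("<second_order_fit> k2 = %.4g 1/(M s) (SE %.2g)\n", x$k2, x$se))
  invisible(x)
}

#' Two-stage inactivation analysis
#'
#' Convenience wrapper: fits each time course (one per concentration) to a
#' single exponential, then regresses k_obs on concentration through the
#' origin to obtain the apparent second-order rate constant.
#'
#' @param timecourses data.frame with columns `concentration_M`, `time_s`,
#'   `activity_pct` (and optionally `condition`).
#' @param ... Passed on to [fit_inactivation()].
#' @return List with `per_concentration` (data.frame: concentration_M,
#'   k_obs, se, t_half, t_half_interpolated) and `second_order`
#'   (a `second_order_fit`).
#' @export
fit_inactivation_series <- function(timecourses, ...) {
  need <- c("concentration_M", "time_s", "activity_pct")
  miss <- setdiff(need, names(timecourses))
  if (length(miss) > 0L) {
    stop(sprintf("timecourse table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  concs <- sort(unique(timecourses$concentration_M))
  per <- do.call(rbind, lapply(concs, function(cc) {
    d <- timecourses[timecourses$concentration_M == cc, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    f <- fit_inactivation(d$time_s, d$activity_pct, ...)
    data.frame(concentration_M = cc, k_obs = f$k_obs, se = f$se,
               t_half = f$t_half,
               t_half_interpolated = f$t_half_interpolated)
  }))
  list(per_concentration = per,
       second_order = fit_second_order(per$concentration_M, per$k_obs))
}

#' Activity recovery after reductant treatment
#'
#' @param activity_after Activity after treatment (e.g. U/mg).
#' @param initial Initial activity in the same units (> 0).
#' @return Recovery in percent of initial.
#' @export
recovery_percent <- function(activity_after, initial) {
  if (initial <= 0) stop("initial activity must be > 0")
  100 * activity_after / initial
}

#' Michaelis-Menten fit with kcat conventions
#'
#' Nonlinear least-squares fit of v = Vmax * S / (Km + S) to initial-rate
#' data. kcat is computed per native enzyme molecule using the supplied
#' native molar mass — by default the homotetramer (4 x 35 363 g/mol),
#' which is the convention under which specific activity in U/mg converts
#' to the published turnover numbers; pass the subunit mass for per-site
#' turnover.
#'
#' @param substrate_mM Substrate concentrations (mmol/L).
#' @param rate Initial rates (U/mg).
#' @param native_molar_mass Native enzyme molar mass in g/mol (default
#'   4 x 35363 for the homotetramer).
#' @return List of class `mm_fit` with `Vmax` (U/mg), `Km` (mM), their
#'   standard errors, `kcat` (1/s) and `kcat_over_Km` (1/(M s)).
#' @export
fit_mm <- function(substrate_mM, rate, native_molar_mass = 4 * 35363) {
  stopifnot(length(substrate_mM) == length(rate))
  if (length(substrate_mM) < 4L) stop("need at least 4 substrate concentrations")
  if (all(rate <= 0)) stop("no positive rates to fit")
  dat <- data.frame(S = substrate_mM, v = rate)
  v0 <- max(dat$v)
  km0 <- dat$S[which.min(abs(dat$v - v0 / 2))]
  if (km0 <= 0) km0 <- stats::median(dat$S[dat$S > 0])
  if (max(dat$S) < 2 * km0 || min(dat$S[dat$S > 0]) > km0) {
    warning("substrate grid does not clearly span Km; estimates may be poor")
  }
  nf <- stats::nls(v ~ Vmax * S / (Km + S), data = dat,
                   start = list(Vmax = v0, Km = km0),
                   control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                                warnOnly = TRUE))
  cf <- summary(nf)$coefficients
  Vmax <- cf["Vmax", "Estimate"]; Km <- cf["Km", "Estimate"]
  # U/mg = umol/min/mg = 1e-3 mol/min/g; * M g/mol / 60 s -> 1/s
  kcat <- Vmax * 1e-3 * native_molar_mass / 60
  out <- list(Vmax = Vmax, Vmax_se = cf["Vmax", "Std. Error"],
              Km = Km, Km_se = cf["Km", "Std. Error"],
              kcat = kcat,
              kcat_over_Km = kcat / (Km * 1e-3),
              native_molar_mass = native_molar_mass)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> Vmax = %.4g U/mg, Km = %.4g mM, kcat = %.4g 1/s, kcat/Km = %.3g 1/(M s)\n",
    x$Vmax, x$Km, x$kcat, x$kcat_over_Km))
  invisible(x)
}

#' Turnover number from specific activity
#'
#' @param vmax Specific activity (U/mg).
#' @param native_molar_mass Native molar mass (g/mol).
#' @return kcat in 1/s.
#' @export
kcat_from_vmax <- function(vmax, native_molar_mass = 4 * 35363) {
  vmax * 1e-3 * native_molar_mass / 60
}

#' Read an activity time-course CSV
#'
#' @param path CSV with columns `condition`, `concentration`, `time_s`,
#'   `activity_pct` (`concentration` in mol/L, or a `concentration_M`
#'   column directly).
#' @return data.frame with a `concentration_M` column.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("time-course CSV not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$concentration_M) && !is.null(d$concentration)) {
    d$concentration_M <- d$concentration
  }
  need <- c("concentration_M", "time_s", "activity_pct")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("time-course CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(d$time_s) | is.na(d$activity_pct))
  if (length(bad) > 0L) {
    stop(sprintf("malformed time-course CSV at row %d", bad[1]))
  }
  d
}

#' Read an initial-rate CSV
#'
#' @param path CSV with columns `substrate_mM`, `rate_U_per_mg`.
#' @return data.frame of rates.
#' @export
read_rates_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("rate CSV not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("substrate_mM", "rate_U_per_mg"), names(d))
  if (length(miss) > 0L) {
    stop(sprintf("rate CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  d
}
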