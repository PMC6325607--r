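# Whole-protein (linear MALDI) mass-shift and occupancy analysis.

#' Mass shift between two intact-protein peaks
#'
#' @param reference Reference (e.g. untreated) peak mass in Da, or a list
#'   with a `mass` field.
#' @param treated Treated peak mass in Da, or a list with a `mass` field.
#' @return Signed mass shift in Da (treated minus reference).
#' @examples
#' mass_shift(35363, 36134)  # 771
#' @export
mass_shift <- function(reference, treated) {
  r <- if (is.list(reference)) reference$mass else reference
  t <- if (is.list(treated)) treated$mass else treated
  t - r
}

#' Classify an intact-mass shift as CoAlation-consistent
#'
#' A shift within `tol` Da of the exact S-CoAlation delta (765.10 Da) is
#' labelled consistent with one CoA per subunit; the default +/- 10 Da
#' reflects linear-MALDI mass accuracy at ~35 kDa.
#'
#' @param shift Observed mass shift in Da.
#' @param expected Expected CoAlation shift (default 765.09956 Da).
#' @param tol Classification tolerance in Da (default 10).
#' @return Logical: is the shift CoAlation-consistent?
#' @export
classify_shift <- function(shift, expected = 765.09956, tol = 10) {
  abs(shift - expected) <= tol
}

#' Modification occupancy from a two-peak intensity ratio
#'
#' Fraction of subunits carrying the modification, read from the relative
#' intensities of the unmodified and modified intact-mass peaks.
#'
#' @param unmodified_intensity Intensity of the unmodified peak.
#' @param modified_intensity Intensity of the modified peak.
#' @return Occupancy fraction in \[0, 1\].
#' @examples
#' occupancy(30, 70)  # 0.70
#' @export
occupancy <- function(unmodified_intensity, modified_intensity) {
  if (unmodified_intensity < 0 || modified_intensity < 0) {
    stop("intensities must be >= 0")
  }
  if (unmodified_intensity == 0 && modified_intensity == 0) {
    stop("both peak intensities are zero")
  }
  modified_intensity / (modified_intensity + unmodified_intensity)
}

#' Read an intact-mass peak list from CSV
#'
#' @param path CSV with columns `mass`, `intensity` and optionally `label`.
#' @return data.frame of peaks.
#' @export
read_intact_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("intact-mass CSV not found: %s", path))
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("mass", "intensity"), names(pk))
  if (length(miss) > 0L) {
    stop(sprintf("intact-mass CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (any(pk$mass <= 0)) stop("peak masses must be > 0")
  pk
}

#' Intact-mass shift and occupancy report
#'
#' Given reference and treated peak lists (each the dominant unmodified
#' peak plus, for the treated sample, the modified peak), computes the
#' mass shift, its CoAlation classification and the occupancy.
#'
#' @param reference data.frame of reference peaks (`mass`, `intensity`).
#' @param treated data.frame of treated peaks.
#' @param expected Expected modification delta in Da.
#' @param tol Classification tolerance in Da.
#' @return List with `reference_mass`, `unmodified_mass`, `modified_mass`,
#'   `shift`, `coalation_consistent`, `occupancy`.
#' @export
intact_report <- function(reference, treated, expected = 765.09956,
                          tol = 10) {
  ref_peak <- reference[which.max(reference$intensity), ]
  # treated: unmodified peak = nearest to reference; modified = nearest to
  # reference + expected shift
  d_un <- abs(treated$mass - ref_peak$mass)
  i_un <- which.min(d_un)
  d_mod <- abs(treated$mass - (ref_peak$mass + expected))
  i_mod <- which.min(d_mod)
  if (i_un == i_mod) stop("treated peak list does not resolve a modified peak")
  shift <- mass_shift(ref_peak$mass, treated$mass[i_mod])
  list(
    reference_mass = ref_peak$mass,
    unmodified_mass = treated$mass[i_un],
    modified_mass = treated$mass[i_mod],
    shift = shift,
    coalation_consistent = classify_shift(shift, expected, tol),
    occupancy = occupancy(treated$intensity[i_un], treated$intensity[i_mod])
  )
}
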