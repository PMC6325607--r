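# Orchestration of the two workflows: identification (digest -> enumerate
# -> match -> diagnostic scan -> annotate -> localize) and redox
# biochemistry (kinetics, pKa, thiols, intact mass).

#' Default run configuration
#'
#' Mirrors the acquisition and search settings of the reference workflow:
#' precursor and fragment tolerance 0.5 Da, diagnostic-loss tolerance
#' 1.0 Da, charge range 1-4, MS1 window m/z 1000-1600, one missed
#' cleavage.
#'
#' @param ... Named overrides of any default.
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    precursor_tolerance = 0.5,
    fragment_tolerance = 0.5,
    diagnostic_tolerance = 1.0,
    min_losses = 2L,
    min_rel_intensity = 0.05,
    charges = 1:4,
    ms1_window = c(1000, 1600),
    max_missed = 1L,
    max_coalations = 1L,
    allow_disulfide = TRUE,
    allow_unmodified = FALSE,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric values
#' are coerced; comma-separated values become vectors. Unset keys keep
#' their defaults.
#'
#' @param path Path to the config file.
#' @return A config list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (identical(val, "TRUE") || identical(val, "FALSE")) {
      val <- as.logical(val)
    }
    overrides[[key]] <- val
  }
  do.call(default_config, overrides)
}

.log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[coalscan] %-22s in: %-6d out: %d", stage, n_in, n_out))
}

#' Run the identification workflow
#'
#' Chains Lys-C digestion, peptidoform enumeration, precursor matching,
#' CoA diagnostic neutral-loss scanning, spectrum annotation and (when a
#' spectrum matches several site-permutation candidates) modification-site
#' localization. Deterministic given inputs and configuration; per-stage
#' input/output counts are logged to stderr.
#'
#' @param fasta Path to the protein FASTA file.
#' @param precursors Path to the precursor observation CSV (`mz`,
#'   `charge`, optional `intensity`).
#' @param mgf Optional path to an MGF file of MS/MS spectra.
#' @param out_dir Output directory for TSV/JSON reports (created).
#' @param config Configuration list from [default_config()].
#' @param catalog Modification catalog.
#' @return Invisibly, a list with `identifications` (report data.frame),
#'   `scans` (data.frame of per-spectrum diagnostic verdicts),
#'   `localizations` (list of `site_localization` results).
#' @export
run_identify <- function(fasta, precursors, mgf = NULL, out_dir = ".",
                         config = default_config(),
                         catalog = modification_catalog()) {
  proteins <- read_fasta(fasta)
  observations <- read_precursors_csv(precursors)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  forms <- list()
  n_pep <- 0L
  for (i in seq_len(nrow(proteins))) {
    dig <- digest_lysc(proteins$sequence[i], max_missed = config$max_missed,
                       protein_id = proteins$id[i])
    n_pep <- n_pep + nrow(dig)
    for (j in seq_len(nrow(dig))) {
      if (!grepl("C", dig$sequence[j], fixed = TRUE)) next
      forms <- c(forms, enumerate_forms(
        dig$sequence[j], catalog = catalog,
        max_coalations = config$max_coalations,
        allow_disulfide = config$allow_disulfide,
        allow_unmodified = config$allow_unmodified,
        start = dig$start[j], end = dig$end[j],
        protein = dig$protein[j]
      ))
    }
  }
  .log_stage("digest", nrow(proteins), n_pep)
  .log_stage("enumerate_forms", n_pep, length(forms))

  matches <- match_precursors(forms, observations,
                              tolerance = config$precursor_tolerance,
                              charges = config$charges,
                              ms1_window = config$ms1_window)
  .log_stage("match_precursors", nrow(observations), nrow(matches))
  report <- identification_table(matches)
  write_identification_report(report,
                              tsv = file.path(out_dir, "identifications.tsv"),
                              json = file.path(out_dir, "identifications.json"))

  scans <- data.frame(spectrum = character(), precursor_mz = numeric(),
                      charge = integer(), n_losses_matched = integer(),
                      coalation_candidate = logical(),
                      stringsAsFactors = FALSE)
  localizations <- list()
  if (!is.null(mgf)) {
    spectra <- read_mgf(mgf)
    for (si in seq_along(spectra)) {
      sp <- spectra[[si]]
      sc <- diagnostic_scan(sp, tolerance = config$diagnostic_tolerance,
                            min_losses = config$min_losses,
                            min_rel_intensity = config$min_rel_intensity)
      scans <- rbind(scans, data.frame(
        spectrum = if (nzchar(sp$title)) sp$title else sprintf("spectrum_%d", si),
        precursor_mz = sp$precursor_mz, charge = sp$precursor_charge,
        n_losses_matched = sc$n_losses_matched,
        coalation_candidate = sc$verdict, stringsAsFactors = FALSE
      ))
      # site localization among forms consistent with this precursor
      m_obs <- neutral_mass(sp$precursor_mz, sp$precursor_charge)
      cand <- Filter(function(f) {
        abs(f$neutral_mass - m_obs) <= config$precursor_tolerance *
          sp$precursor_charge
      }, forms)
      if (length(cand) >= 2L) {
        seqs <- vapply(cand, `[[`, character(1), "sequence")
        masses <- vapply(cand, `[[`, numeric(1), "neutral_mass")
        grp <- cand[seqs == seqs[1] & abs(masses - masses[1]) < 1e-6]
        if (length(grp) >= 2L) {
          localizations[[length(localizations) + 1L]] <-
            localize_site(sp, grp, tolerance = config$fragment_tolerance)
        }
      }
    }
    .log_stage("diagnostic_scan", length(spectra), sum(scans$coalation_candidate))
  }
  utils::write.table(scans, file.path(out_dir, "scan_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report) == 0L) warning("no precursor matches; empty report written")
  invisible(list(identifications = report, scans = scans,
                 localizations = localizations))
}

#' Run the redox-biochemistry workflow
#'
#' Fits every supplied biochemical input and writes one JSON report per
#' analysis: two-stage inactivation kinetics (per-concentration k_obs and
#' apparent second-order rate constant), Michaelis-Menten parameters with
#' kcat conventions, cysteine pKa, free thiols per subunit, and
#' intact-mass shift/occupancy.
#'
#' @param out_dir Output directory (created).
#' @param timecourses Optional path to a time-course CSV
#'   (`concentration_M`, `time_s`, `activity_pct`).
#' @param rates Optional path to an initial-rate CSV (`substrate_mM`,
#'   `rate_U_per_mg`).
#' @param titration Optional path to a titration CSV (`pH`,
#'   `activity_pct`).
#' @param intact_reference,intact_treated Optional paths to intact-mass
#'   CSVs (`mass`, `intensity`).
#' @param thiols Optional data.frame or CSV path with columns `A412`,
#'   `conc_M`.
#' @param native_molar_mass Native molar mass for kcat (g/mol).
#' @return Invisibly, a named list of the fit results.
#' @export
run_biochem <- function(out_dir = ".", timecourses = NULL, rates = NULL,
                        titration = NULL, intact_reference = NULL,
                        intact_treated = NULL, thiols = NULL,
                        native_molar_mass = 4 * 35363) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  wj <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  if (!is.null(timecourses)) {
    tc <- read_timecourse_csv(timecourses)
    fit <- fit_inactivation_series(tc)
    results$kinetics <- fit
    wj(list(per_concentration = fit$per_concentration,
            k2 = fit$second_order$k2, k2_se = fit$second_order$se),
       "kinetics")
  }
  if (!is.null(rates)) {
    rt <- read_rates_csv(rates)
    fit <- fit_mm(rt$substrate_mM, rt$rate_U_per_mg,
                  native_molar_mass = native_molar_mass)
    results$mm <- fit
    wj(unclass(fit), "michaelis_menten")
  }
  if (!is.null(titration)) {
    ti <- read_titration_csv(titration)
    fit <- fit_pka(ti$pH, ti$activity_pct)
    results$pka <- fit
    wj(list(pKa = fit$pKa, pKa_se = fit$pKa_se, top = fit$top,
            bottom = fit$bottom), "pka")
  }
  if (!is.null(thiols)) {
    th <- if (is.character(thiols)) utils::read.csv(thiols) else thiols
    tp <- thiols_per_subunit(th$A412, th$conc_M)
    results$thiols <- data.frame(A412 = th$A412, conc_M = th$conc_M,
                                 thiols_per_subunit = tp)
    wj(results$thiols, "thiols")
  }
  if (!is.null(intact_reference) && !is.null(intact_treated)) {
    ref <- read_intact_csv(intact_reference)
    trt <- read_intact_csv(intact_treated)
    rep_ <- intact_report(ref, trt)
    results$intact <- rep_
    wj(rep_, "intact_mass")
  }
  invisible(results)
}
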