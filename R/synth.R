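# Seeded synthetic-data generators for every input the pipeline consumes.
# All generators are pure functions of their arguments: the same seed and
# configuration reproduce the same output.

#' Simulate a centroided CID MS/MS spectrum of a modified peptidoform
#'
#' Emits the full theoretical b/y ladder (with CoA remnant variants for
#' CoAlated forms), optionally the three precursor-minus-CoA-fragment
#' diagnostic loss peaks, Gaussian m/z jitter and uniform noise peaks over
#' the MS2 acquisition window.
#'
#' @param form A `peptide_form`.
#' @param precursor_charge Precursor charge state (default 3).
#' @param fragment_charge Maximum fragment charge (default 1).
#' @param include_losses Emit the diagnostic neutral-loss peaks when the
#'   form is CoAlated (default TRUE).
#' @param intensity_model `"uniform"` (all fragment intensities 100) or
#'   `"random"` (uniform on \[20, 100\]).
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (default 0).
#' @param n_noise_peaks Number of uniform noise peaks (default 0).
#' @param noise_max_rel Noise intensity ceiling as a fraction of the base
#'   peak (default 0.1).
#' @param mz_range MS2 window for noise peaks (default c(50, 2000)).
#' @param rules CoA fragmentation rules.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return An `ms2_spectrum`.
#' @export
simulate_ms2 <- function(form, precursor_charge = 3L, fragment_charge = 1L,
                         include_losses = TRUE,
                         intensity_model = c("uniform", "random"),
                         mz_jitter_sd = 0, n_noise_peaks = 0L,
                         noise_max_rel = 0.1, mz_range = c(50, 2000),
                         rules = coa_frag_rules(), seed = NULL) {
  intensity_model <- match.arg(intensity_model)
  if (mz_jitter_sd < 0) stop("mz_jitter_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ladder <- fragment_ladder(form, max_charge = fragment_charge, rules = rules)
  mzv <- ladder$mz
  inten <- if (intensity_model == "uniform") {
    rep(100, nrow(ladder))
  } else {
    stats::runif(nrow(ladder), 20, 100)
  }
  prec_mz <- mz(form$neutral_mass, precursor_charge)
  coalated <- length(.coalated_positions(form)) > 0L
  if (include_losses && coalated) {
    loss_mz <- (form$neutral_mass + precursor_charge * .mass_table$proton -
                  rules$losses) / precursor_charge
    mzv <- c(mzv, loss_mz)
    inten <- c(inten, rep(100, length(loss_mz)))
  }
  if (mz_jitter_sd > 0) {
    mzv <- mzv + stats::rnorm(length(mzv), 0, mz_jitter_sd)
  }
  if (n_noise_peaks > 0L) {
    mzv <- c(mzv, stats::runif(n_noise_peaks, mz_range[1], mz_range[2]))
    inten <- c(inten, stats::runif(n_noise_peaks, 0,
                                   noise_max_rel * max(inten)))
  }
  ms2_spectrum(prec_mz, precursor_charge, mzv, inten,
               title = sprintf("synthetic %s (%d+)", form$label,
                               precursor_charge))
}

#' Simulate exponential inactivation time courses
#'
#' Generates A(t) = 100 * exp(-k2 * C * t) * (1 + eps) per concentration,
#' with multiplicative Gaussian noise truncated at 0.
#'
#' @param k2 Apparent second-order rate constant (1/(M s)).
#' @param concentrations_M Reagent concentrations (mol/L, > 0).
#' @param times_s Time grid in seconds (default 0-20 min every minute).
#' @param noise_sd Relative noise SD (default 0; e.g. 0.03 for 3%).
#' @param condition Condition label stem.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return data.frame with columns `condition`, `concentration_M`,
#'   `time_s`, `activity_pct`.
#' @export
simulate_timecourses <- function(k2, concentrations_M,
                                 times_s = seq(0, 1200, by = 60),
                                 noise_sd = 0, condition = "reagent",
                                 seed = NULL) {
  if (any(concentrations_M <= 0)) stop("concentrations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(concentrations_M, function(cc) {
    a <- 100 * exp(-k2 * cc * times_s)
    if (noise_sd > 0) {
      a <- pmax(a * (1 + stats::rnorm(length(a), 0, noise_sd)), 0)
    }
    data.frame(condition = sprintf("%s_%g_M", condition, cc),
               concentration_M = cc, time_s = times_s, activity_pct = a)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a pH-activity titration
#'
#' Evaluates the single-site sigmoid
#' R(pH) = bottom + (top - bottom) / (1 + 10^(pH - pKa)) with additive
#' Gaussian noise in percentage points, truncated at 0.
#'
#' @param pKa True pKa.
#' @param top,bottom Plateau activities (%).
#' @param pH pH grid (must span the pKa).
#' @param noise_sd Additive noise SD in percentage points.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return data.frame with columns `pH`, `activity_pct`.
#' @export
simulate_titration <- function(pKa = 5.82, top = 100, bottom = 0,
                               pH = seq(4, 9, length.out = 12),
                               noise_sd = 0, seed = NULL) {
  if (min(pH) > pKa || max(pH) < pKa) stop("pH grid must span the pKa")
  if (!is.null(seed)) set.seed(seed)
  r <- bottom + (top - bottom) / (1 + 10^(pH - pKa))
  if (noise_sd > 0) r <- pmax(r + stats::rnorm(length(r), 0, noise_sd), 0)
  data.frame(pH = pH, activity_pct = r)
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' @param Vmax True Vmax (U/mg).
#' @param Km_mM True Km (mM).
#' @param substrate_mM Substrate grid (must span Km).
#' @param noise_sd Relative noise SD.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return data.frame with columns `substrate_mM`, `rate_U_per_mg`.
#' @export
simulate_mm <- function(Vmax = 152, Km_mM = 1.23,
                        substrate_mM = c(0.1, 0.25, 0.5, 1, 2, 4, 7, 10),
                        noise_sd = 0, seed = NULL) {
  if (min(substrate_mM) > Km_mM || max(substrate_mM) < Km_mM) {
    stop("substrate grid must span Km")
  }
  if (!is.null(seed)) set.seed(seed)
  v <- Vmax * substrate_mM / (Km_mM + substrate_mM)
  if (noise_sd > 0) v <- pmax(v * (1 + stats::rnorm(length(v), 0, noise_sd)), 0)
  data.frame(substrate_mM = substrate_mM, rate_U_per_mg = v)
}

#' Synthetic carrier protein embedding the two reference peptides
#'
#' A synthetic (not naturally occurring) 300-residue protein whose Lys-C
#' digest places the two published cysteine-containing reference peptides
#' at their native coordinates: YEGQDIVSNASCTTNCLAPLAK at 138-159 (active
#' site Cys149/Cys153) and GVLGYTEDDVVSTDFNGEVCTSVFDAK at 269-295
#' (Cys288). Filler segments are cysteine- and lysine-free except for the
#' lysines that delimit the spans.
#'
#' @return A list with `id`, `description` and `sequence`.
#' @export
synthetic_gapdh_protein <- function() {
  pep1 <- "YEGQDIVSNASCTTNCLAPLAK"  # 138-159
  pep2 <- "GVLGYTEDDVVSTDFNGEVCTSVFDAK"  # 269-295
  filler <- function(n) {
    # deterministic K/C-free filler
    alphabet <- c("A", "G", "S", "T", "V", "L", "D", "E", "N", "Q")
    paste(alphabet[(seq_len(n) - 1L) %% length(alphabet) + 1L], collapse = "")
  }
  seg1 <- paste0(filler(70), "K", filler(65), "K")   # 1-137, K at 71 and 137
  stopifnot(nchar(seg1) == 137L)
  seg2 <- paste0(filler(54), "K", filler(53), "K")   # 160-268, K at 214 and 268
  stopifnot(nchar(seg2) == 109L)
  seg3 <- filler(5)                                   # 296-300 C-terminal tail
  seqn <- paste0(seg1, pep1, seg2, pep2, seg3)
  stopifnot(substr(seqn, 138, 159) == pep1, substr(seqn, 269, 295) == pep2)
  list(id = "synthetic_gapdh",
       description = "synthetic carrier protein for the reference peptides",
       sequence = seqn)
}

#' Reference-peptide identification fixture
#'
#' Bundles the published identification inputs at desk scale: the
#' synthetic carrier protein, the two reference peptides, their modified
#' forms, the published precursor observation table (observed m/z, charge)
#' and a synthetic CoAlated CID spectrum with diagnostic losses.
#'
#' @param seed Seed for the synthetic spectrum.
#' @return List with `protein`, `peptides` (digest rows for the two
#'   spans), `observations` (data.frame: mz, charge, intensity,
#'   condition), `coalated_form` and `spectrum`.
#' @export
identification_fixture <- function(seed = 1L) {
  prot <- synthetic_gapdh_protein()
  dig <- digest_lysc(prot$sequence, max_missed = 1L, protein_id = prot$id)
  peptides <- dig[dig$sequence %in% c("YEGQDIVSNASCTTNCLAPLAK",
                                      "GVLGYTEDDVVSTDFNGEVCTSVFDAK"), ]
  # published observed precursor ions (NaOCl-stressed and nonstressed)
  observations <- data.frame(
    mz = c(1040.765, 1148.556, 1202.076, 1206.580, 1462.677,
           1206.589, 1213.596, 1462.686),
    charge = c(3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    intensity = NA_real_,
    condition = c(rep("NaOCl", 5L), rep("nonstressed", 3L)),
    stringsAsFactors = FALSE
  )
  p1 <- peptides[peptides$sequence == "YEGQDIVSNASCTTNCLAPLAK", ][1, ]
  coalated_form <- peptide_form(
    p1$sequence,
    site_states = c("12" = "CoAlation", "16" = "CAM"),
    start = p1$start, end = p1$end, protein = prot$id
  )
  spectrum <- simulate_ms2(coalated_form, precursor_charge = 3L,
                           include_losses = TRUE, seed = seed)
  list(protein = prot, peptides = peptides, observations = observations,
       coalated_form = coalated_form, spectrum = spectrum)
}

#' Write the identification fixture to disk
#'
#' Writes the synthetic carrier FASTA, the precursor CSV and the synthetic
#' MGF into a directory, ready for [run_identify()].
#'
#' @param dir Output directory (created if absent).
#' @param seed Seed for the synthetic spectrum.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_identification_fixture <- function(dir, seed = 1L) {
  fx <- identification_fixture(seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "synthetic_gapdh.fasta")
  writeLines(c(sprintf(">%s %s", fx$protein$id, fx$protein$description),
               gsub("(.{60})", "\\1\n", fx$protein$sequence)), fasta)
  prec <- file.path(dir, "precursors.csv")
  utils::write.csv(fx$observations, prec, row.names = FALSE)
  mgf <- file.path(dir, "spectra.mgf")
  write_mgf(fx$spectrum, mgf)
  invisible(list(fasta = fasta, precursors = prec, mgf = mgf))
}
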