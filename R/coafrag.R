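# b/y fragment ladders with CoA remnant chemistry, diagnostic neutral-loss
# scanning, spectrum annotation and modification-site localization.

#' CoA fragmentation rules for CID
#'
#' Under collision-induced dissociation a CoAlated peptide preferentially
#' fragments within the CoA moiety, releasing characteristic neutral
#' losses of nominally 410, 428 and 508 Da (with hydrogen-shift variants
#' 409, 427, 507) while the cysteine retains the complementary remnant
#' (+258, +338, +356 Da nominal). The full CoAlation delta is
#' +765.09956 Da (CoA minus two hydrogens).
#'
#' @return List with fields `losses`, `loss_variants`, `remnants`
#'   (nominal Da) and `full_delta` (exact Da).
#' @export
coa_frag_rules <- function() {
  list(
    losses = c(410, 428, 508),
    loss_variants = c(409, 427, 507),
    remnants = c(258, 338, 356),
    full_delta = 765.09956
  )
}

#' Construct an MS2 spectrum object
#'
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge state.
#' @param mz Numeric vector of centroided peak m/z values.
#' @param intensity Parallel vector of intensities (>= 0).
#' @param title Optional title string.
#' @return An object of class `ms2_spectrum`; peaks are kept sorted by m/z.
#' @export
ms2_spectrum <- function(precursor_mz, precursor_charge, mz, intensity,
                         title = "") {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  obj <- list(precursor_mz = precursor_mz,
              precursor_charge = as.integer(precursor_charge),
              peaks = data.frame(mz = mz[o], intensity = intensity[o]),
              title = title)
  class(obj) <- "ms2_spectrum"
  obj
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f (%d+), %d peaks\n",
              x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

# per-residue mass deltas of a form (per-site states + disulphide),
# as a numeric vector over residue positions
.site_delta_vector <- function(form, catalog = modification_catalog()) {
  n <- nchar(form$sequence)
  d <- numeric(n)
  if (length(form$site_states) > 0L) {
    pos <- as.integer(names(form$site_states))
    keep <- form$site_states != "unmodified"
    d[pos[keep]] <- catalog$exact_delta[match(form$site_states[keep],
                                              catalog$name)]
  }
  ss <- catalog$exact_delta[catalog$name == "disulphide"]
  for (pr in form$disulfide_pairs) d[pr[1]] <- d[pr[1]] + ss
  d
}

.coalated_positions <- function(form) {
  if (length(form$site_states) == 0L) return(integer(0))
  as.integer(names(form$site_states))[form$site_states == "CoAlation"]
}

#' Theoretical b/y fragment ladder of a modified peptidoform
#'
#' Generates all b and y backbone ions at charges 1..`max_charge`. For
#' every ion that contains a CoAlated cysteine, four variants are emitted:
#' the intact CoAlation (`fullCoA`) and the three CID remnant states in
#' which only +258/+338/+356 Da stay on the cysteine. For
#' disulphide-bonded forms, cleavage sites inside the ring span are
#' suppressed by default (the cyclic constraint keeps both halves
#' connected).
#'
#' @param form A `peptide_form`.
#' @param max_charge Maximum fragment charge (default 1).
#' @param rules CoA fragmentation rules.
#' @param catalog Modification catalog.
#' @param ring_open Emit ions for cleavage sites inside a disulphide ring.
#' @return data.frame with columns `series` ("b"/"y"), `ordinal`, `charge`,
#'   `remnant` ("none", "fullCoA", "remnant258", "remnant338",
#'   "remnant356") and `mz`.
#' @export
fragment_ladder <- function(form, max_charge = 1L, rules = coa_frag_rules(),
                            catalog = modification_catalog(),
                            ring_open = FALSE) {
  n <- nchar(form$sequence)
  if (n < 2L) stop("cannot fragment a single-residue peptide")
  aa <- strsplit(form$sequence, "", fixed = TRUE)[[1]]
  res <- .mass_table$residues[aa]
  deltas <- .site_delta_vector(form, catalog)
  coa_pos <- .coalated_positions(form)
  water <- .mass_table$water
  proton <- .mass_table$proton
  # suppressed cleavage sites: bonds strictly inside a disulphide ring
  blocked <- logical(n - 1L)
  if (!ring_open && length(form$disulfide_pairs) > 0L) {
    for (pr in form$disulfide_pairs) {
      lo <- min(pr); hi <- max(pr)
      if (hi - lo >= 1L) blocked[lo:(hi - 1L)] <- TRUE
    }
  }
  rows <- list()
  emit <- function(series, ordinal, base_neutral, has_coa) {
    variants <- if (has_coa) {
      data.frame(
        remnant = c("fullCoA", "remnant258", "remnant338", "remnant356"),
        shift = c(0, rules$remnants - rules$full_delta),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(remnant = "none", shift = 0, stringsAsFactors = FALSE)
    }
    for (z in seq_len(max_charge)) {
      for (k in seq_len(nrow(variants))) {
        rows[[length(rows) + 1L]] <<- data.frame(
          series = series, ordinal = ordinal, charge = z,
          remnant = variants$remnant[k],
          mz = (base_neutral + variants$shift[k] + z * proton) / z,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (i in seq_len(n - 1L)) {
    if (blocked[i]) next
    # b_i: residues 1..i; neutral b fragment mass = sum(res) + deltas
    b_neutral <- sum(res[1:i]) + sum(deltas[1:i])
    emit("b", i, b_neutral, any(coa_pos <= i))
    # y_{n-i}: residues (i+1)..n; neutral = sum + water
    y_neutral <- sum(res[(i + 1L):n]) + sum(deltas[(i + 1L):n]) + water
    emit("y", n - i, y_neutral, any(coa_pos > i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnostic CoA neutral-loss scan of an MS/MS spectrum
#'
#' Searches the spectrum for product ions corresponding to the precursor
#' minus each characteristic CoA neutral loss (nominal 410/428/508 Da and
#' their hydrogen-shift variants 409/427/507). Each loss is searched at
#' the precursor charge and every lower charge, i.e. at
#' \eqn{(M + z' m_p - L)/z'} for \eqn{z' = z, z-1, \ldots, 1}. The
#' spectrum is flagged as a CoAlation candidate when at least `min_losses`
#' distinct losses are matched above `min_rel_intensity` of the base peak.
#'
#' @param spectrum An `ms2_spectrum` with precursor m/z and charge.
#' @param rules CoA fragmentation rules.
#' @param tolerance Match tolerance in Da on the product m/z (default 1.0,
#'   absorbing hydrogen-transfer ambiguity on nominal masses).
#' @param min_losses Minimum distinct losses required for a positive
#'   verdict (default 2).
#' @param min_rel_intensity Minimum peak intensity as a fraction of the
#'   base peak (default 0.05).
#' @return List of class `coa_scan` with `hits` (data.frame: loss,
#'   variant, charge, expected_mz, matched_mz, intensity,
#'   rel_intensity), `n_losses_matched` and logical `verdict`.
#' @export
diagnostic_scan <- function(spectrum, rules = coa_frag_rules(),
                            tolerance = 1.0, min_losses = 2L,
                            min_rel_intensity = 0.05) {
  if (is.null(spectrum$precursor_charge) || is.na(spectrum$precursor_charge)) {
    stop("spectrum has no precursor charge")
  }
  if (is.null(spectrum$precursor_mz) || is.na(spectrum$precursor_mz)) {
    stop("spectrum has no precursor m/z")
  }
  z <- spectrum$precursor_charge
  m_prec <- neutral_mass(spectrum$precursor_mz, z)
  pk <- spectrum$peaks
  base <- if (nrow(pk) > 0L) max(pk$intensity) else 0
  hits <- list()
  for (li in seq_along(rules$losses)) {
    for (variant in c(rules$losses[li], rules$loss_variants[li])) {
      for (zp in seq(z, 1L)) {
        exp_mz <- (m_prec + zp * .mass_table$proton - variant) / zp
        if (nrow(pk) == 0L) next
        d <- abs(pk$mz - exp_mz)
        j <- which.min(d)
        if (d[j] <= tolerance && base > 0 &&
            pk$intensity[j] / base >= min_rel_intensity) {
          hits[[length(hits) + 1L]] <- data.frame(
            loss = rules$losses[li], variant = variant, charge = zp,
            expected_mz = exp_mz, matched_mz = pk$mz[j],
            intensity = pk$intensity[j],
            rel_intensity = pk$intensity[j] / base,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(loss = numeric(), variant = numeric(), charge = integer(),
               expected_mz = numeric(), matched_mz = numeric(),
               intensity = numeric(), rel_intensity = numeric())
  n_losses <- length(unique(hits$loss))
  out <- list(hits = hits, n_losses_matched = n_losses,
              verdict = n_losses >= min_losses)
  class(out) <- "coa_scan"
  out
}

#' @export
print.coa_scan <- function(x, ...) {
  cat(sprintf("<coa_scan> %d/3 diagnostic losses matched; CoAlation %s\n",
              x$n_losses_matched,
              if (x$verdict) "candidate" else "not indicated"))
  invisible(x)
}

#' Annotate an MS/MS spectrum with a peptidoform's fragment ladder
#'
#' Greedy nearest-peak matching of the theoretical b/y ions (with CoA
#' remnant variants) against observed peaks; each observed peak is used at
#' most once. Coverage is the fraction of backbone cleavage positions
#' (b or y, any variant/charge) with at least one matched ion.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param form A `peptide_form`; a warning is issued when the form's mass
#'   is inconsistent with the precursor beyond `precursor_tolerance`.
#' @param tolerance Fragment match tolerance in Da (default 0.5).
#' @param max_charge Maximum fragment charge to consider.
#' @param precursor_tolerance Consistency check tolerance in Da.
#' @return List of class `spectrum_annotation` with `matches` (data.frame
#'   of matched ions), `coverage` and `n_theoretical`.
#' @export
annotate_spectrum <- function(spectrum, form, tolerance = 0.5,
                              max_charge = 1L, precursor_tolerance = 2.0) {
  if (!is.null(spectrum$precursor_mz) && !is.na(spectrum$precursor_mz) &&
      !is.null(spectrum$precursor_charge)) {
    obs_m <- neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
    if (abs(obs_m - form$neutral_mass) > precursor_tolerance) {
      warning(sprintf(
        "form mass %.3f differs from precursor-derived mass %.3f by > %.1f Da",
        form$neutral_mass, obs_m, precursor_tolerance))
    }
  }
  ladder <- fragment_ladder(form, max_charge = max_charge)
  pk <- spectrum$peaks
  used <- rep(FALSE, nrow(pk))
  rows <- list()
  if (nrow(pk) > 0L) {
    for (i in order(ladder$mz)) {
      cand <- which(!used)
      if (length(cand) == 0L) break
      d <- abs(pk$mz[cand] - ladder$mz[i])
      j <- cand[which.min(d)]
      if (abs(pk$mz[j] - ladder$mz[i]) <= tolerance) {
        used[j] <- TRUE
        rows[[length(rows) + 1L]] <- cbind(
          ladder[i, , drop = FALSE],
          data.frame(observed_mz = pk$mz[j], intensity = pk$intensity[j])
        )
      }
    }
  }
  matches <- if (length(rows) > 0L) do.call(rbind, rows) else
    cbind(ladder[0, , drop = FALSE],
          data.frame(observed_mz = numeric(), intensity = numeric()))
  rownames(matches) <- NULL
  # coverage over distinct (series, ordinal) cleavage positions
  all_pos <- unique(paste(ladder$series, ladder$ordinal))
  hit_pos <- unique(paste(matches$series, matches$ordinal))
  out <- list(matches = matches,
              coverage = length(hit_pos) / length(all_pos),
              n_theoretical = nrow(ladder))
  class(out) <- "spectrum_annotation"
  out
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  cat(sprintf("<spectrum_annotation> %d ions matched, coverage %.2f\n",
              nrow(x$matches), x$coverage))
  invisible(x)
}

#' Localize a modification site among candidate peptidoforms
#'
#' Ranks site-permutation candidates (same peptide, same total mass) by an
#' intensity-weighted count of matched site-determining ions — ions whose
#' theoretical m/z differs between at least two candidates. A tie flag is
#' set when the top two scores are equal (e.g. no site-determining ion was
#' observed), in which case the site assignment is ambiguous.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param candidates List of >= 2 `peptide_form` objects sharing sequence
#'   and neutral mass.
#' @param tolerance Fragment tolerance in Da.
#' @param max_charge Maximum fragment charge.
#' @return List of class `site_localization` with `ranking` (data.frame:
#'   label, score, n_site_ions_matched), `tie` flag and `best` (the
#'   winning form, or NULL on a tie).
#' @export
localize_site <- function(spectrum, candidates, tolerance = 0.5,
                          max_charge = 1L) {
  if (length(candidates) < 2L) stop("nothing to localize: need >= 2 candidates")
  seqs <- vapply(candidates, `[[`, character(1), "sequence")
  if (length(unique(seqs)) != 1L) stop("candidates must share one peptide")
  masses <- vapply(candidates, `[[`, numeric(1), "neutral_mass")
  if (diff(range(masses)) > 1e-6) {
    stop("candidates must be site permutations of equal total mass")
  }
  ladders <- lapply(candidates, fragment_ladder, max_charge = max_charge)
  # site-determining ions: (series, ordinal, charge, remnant) keys whose m/z
  # differs across candidates
  key <- function(l) paste(l$series, l$ordinal, l$charge, l$remnant)
  mz_by_key <- lapply(ladders, function(l) {
    stats::setNames(l$mz, key(l))
  })
  all_keys <- unique(unlist(lapply(mz_by_key, names)))
  determining <- vapply(all_keys, function(k) {
    vals <- unlist(lapply(mz_by_key, function(v) v[k]))
    vals <- vals[!is.na(vals)]
    length(vals) < length(candidates) || diff(range(vals)) > 1e-6
  }, logical(1))
  det_keys <- all_keys[determining]
  pk <- spectrum$peaks
  score_one <- function(ladder) {
    l <- ladder[key(ladder) %in% det_keys, , drop = FALSE]
    if (nrow(l) == 0L || nrow(pk) == 0L) return(c(0, 0))
    s <- 0; nmatch <- 0
    base <- max(pk$intensity)
    for (i in seq_len(nrow(l))) {
      d <- abs(pk$mz - l$mz[i])
      j <- which.min(d)
      if (d[j] <= tolerance) {
        s <- s + (if (base > 0) pk$intensity[j] / base else 1)
        nmatch <- nmatch + 1
      }
    }
    c(s, nmatch)
  }
  scored <- t(vapply(ladders, score_one, numeric(2)))
  ranking <- data.frame(
    label = vapply(candidates, `[[`, character(1), "label"),
    score = scored[, 1], n_site_ions_matched = as.integer(scored[, 2]),
    stringsAsFactors = FALSE
  )
  o <- order(-ranking$score)
  ranking <- ranking[o, , drop = FALSE]
  rownames(ranking) <- NULL
  tie <- nrow(ranking) >= 2L &&
    isTRUE(all.equal(ranking$score[1], ranking$score[2], tolerance = 1e-12))
  out <- list(ranking = ranking, tie = tie,
              best = if (tie) NULL else candidates[[o[1]]])
  class(out) <- "site_localization"
  out
}

#' @export
print.site_localization <- function(x, ...) {
  if (x$tie) {
    cat("<site_localization> ambiguous (tie): no site-determining ion decides\n")
  } else {
    cat(sprintf("<site_localization> best: %s (score %.3f)\n",
                x$ranking$label[1], x$ranking$score[1]))
  }
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Minimal Mascot Generic Format reader: BEGIN IONS / END IONS blocks with
#' TITLE, PEPMASS, CHARGE headers and m/z-intensity peak rows.
#'
#' @param path Path to an MGF file.
#' @return List of `ms2_spectrum` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("MGF file not found: %s", path))
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- ""; pepmass <- NA_real_; charge <- NA_integer_
      mzv <- numeric(0); inten <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(gsub("[^0-9]", "", ln))
        } else if (grepl("^[0-9]", ln)) {
          xs <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mzv <- c(mzv, xs[1]); inten <- c(inten, xs[2])
        }
        i <- i + 1L
      }
      spectra[[length(spectra) + 1L]] <-
        ms2_spectrum(pepmass, charge, mzv, inten, title = title)
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra A single `ms2_spectrum` or a list of them.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (nrow(sp$peaks) > 0L) {
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write a spectrum annotation as TSV/JSON
#'
#' @param annotation A `spectrum_annotation`.
#' @param tsv,json Optional output paths.
#' @return Invisibly, the annotation.
#' @export
write_annotation <- function(annotation, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(annotation$matches, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(coverage = annotation$coverage,
           n_theoretical = annotation$n_theoretical,
           matches = annotation$matches),
      json, dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(annotation)
}
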