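# Cysteine-modification catalog, peptidoform enumeration and precursor
# matching.

#' Default cysteine-modification catalog
#'
#' The fixed set of cysteine states considered during identification:
#' carbamidomethylation (CAM, iodoacetamide alkylation), propionamide
#' (acrylamide gel artifact), trioxidation to sulfonic acid, dimedone
#' (sulphenic-acid trap), S-CoAlation (CoA minus 2 H, mixed disulphide
#' with coenzyme A), and the pairwise intramolecular disulphide.
#'
#' @return A data.frame with columns `name`, `target`, `exact_delta` (Da,
#'   monoisotopic), `nominal_delta` (integer Da, as conventionally
#'   printed) and `kind` (`"per_site"` or `"pairwise"`).
#' @export
modification_catalog <- function() {
  data.frame(
    name = c("CAM", "PA", "trioxidation", "dimedone", "CoAlation",
             "disulphide"),
    target = "C",
    exact_delta = c(57.02146, 71.03711, 47.98474, 138.06808, 765.09956,
                    -2.01565),
    nominal_delta = c(57L, 71L, 48L, 138L, 765L, -2L),
    kind = c(rep("per_site", 5L), "pairwise"),
    stringsAsFactors = FALSE
  )
}

#' Locate cysteines in a peptide sequence
#'
#' @param sequence Peptide sequence string.
#' @return Integer vector of 1-based cysteine positions within the peptide.
#' @export
cysteine_positions <- function(sequence) {
  which(strsplit(sequence, "", fixed = TRUE)[[1]] == "C")
}

#' Construct a modified peptidoform
#'
#' A peptidoform is a digested peptide span plus one modification state
#' per cysteine and optional intramolecular disulphide pairs. Its neutral
#' monoisotopic mass is computed on construction.
#'
#' @param sequence Peptide sequence.
#' @param site_states Named character vector: names are cysteine positions
#'   (within the peptide, 1-based), values are catalog modification names
#'   or `"unmodified"`.
#' @param disulfide_pairs List of length-2 integer vectors pairing
#'   cysteine positions; a paired cysteine carries no per-site state.
#' @param start,end Optional residue coordinates in the parent protein.
#' @param protein Parent protein identifier.
#' @param catalog Modification catalog (see [modification_catalog()]).
#' @return An object of class `peptide_form`: a list with fields
#'   `sequence`, `start`, `end`, `protein`, `site_states`,
#'   `disulfide_pairs`, `neutral_mass`, `label`.
#' @export
peptide_form <- function(sequence, site_states = character(),
                         disulfide_pairs = list(), start = 1L,
                         end = nchar(sequence), protein = "protein",
                         catalog = modification_catalog()) {
  cys <- cysteine_positions(sequence)
  pos <- as.integer(names(site_states))
  if (length(site_states) > 0L) {
    if (any(is.na(pos))) stop("site_states must be named by cysteine position")
    if (!all(pos %in% cys)) stop("site_states positions must be cysteines")
    bad <- setdiff(site_states, c(catalog$name[catalog$kind == "per_site"],
                                  "unmodified"))
    if (length(bad) > 0L) stop(sprintf("unknown modification '%s'", bad[1]))
  }
  paired <- unlist(disulfide_pairs)
  if (length(paired) > 0L) {
    if (!all(paired %in% cys)) stop("disulphide positions must be cysteines")
    if (anyDuplicated(paired)) stop("a cysteine can join only one disulphide")
    if (any(paired %in% pos)) {
      stop("a disulphide-paired cysteine cannot carry a per-site state")
    }
  }
  deltas <- numeric(0)
  dpos <- integer(0)
  if (length(site_states) > 0L) {
    keep <- site_states != "unmodified"
    if (any(keep)) {
      deltas <- catalog$exact_delta[match(site_states[keep], catalog$name)]
      dpos <- pos[keep]
    }
  }
  ss_delta <- catalog$exact_delta[catalog$name == "disulphide"]
  deltas <- c(deltas, rep(ss_delta, length(disulfide_pairs)))
  mass <- monoisotopic_mass(sequence, site_deltas = deltas,
                            positions = c(dpos, rep(1L, length(disulfide_pairs))))
  obj <- list(sequence = sequence, start = as.integer(start),
              end = as.integer(end), protein = protein,
              site_states = site_states, disulfide_pairs = disulfide_pairs,
              neutral_mass = mass)
  obj$label <- form_label(obj)
  class(obj) <- "peptide_form"
  obj
}

#' Human-readable label of a peptidoform
#'
#' Annotates each modified cysteine in the sequence, e.g.
#' `YEGQDIVSNASC[CoAlation]TTNC[CAM]LAPLAK`, with `[SS]` for
#' disulphide-paired cysteines.
#'
#' @param form A `peptide_form`.
#' @return A single string.
#' @export
form_label <- function(form) {
  aa <- strsplit(form$sequence, "", fixed = TRUE)[[1]]
  tags <- rep("", length(aa))
  if (length(form$site_states) > 0L) {
    pos <- as.integer(names(form$site_states))
    keep <- form$site_states != "unmodified"
    tags[pos[keep]] <- sprintf("[%s]", form$site_states[keep])
  }
  for (p in unlist(form$disulfide_pairs)) tags[p] <- "[SS]"
  paste0(aa, tags, collapse = "")
}

#' @export
print.peptide_form <- function(x, ...) {
  cat(sprintf("<peptide_form> %s (%d-%d)  M = %.4f Da\n",
              x$label, x$start, x$end, x$neutral_mass))
  invisible(x)
}

#' Enumerate all modified peptidoforms of a peptide
#'
#' Assigns one per-site state to every cysteine (from the per-site entries
#' of the catalog) and, when `allow_disulfide`, additionally emits every
#' intramolecular disulphide pairing of two cysteines with all state
#' assignments of the remaining cysteines. Free (unmodified) cysteines are
#' excluded by default because identification workflows alkylate all free
#' thiols with iodoacetamide before digestion.
#'
#' @param sequence Peptide sequence (or a one-row digest data.frame row).
#' @param catalog Modification catalog.
#' @param max_coalations Maximum CoAlation count per peptide (default 1).
#' @param allow_disulfide Enumerate intramolecular disulphide pairings.
#' @param allow_unmodified Include the free-thiol state per cysteine.
#' @param start,end,protein Span coordinates carried into the forms.
#' @return A list of `peptide_form` objects (empty when the peptide has no
#'   cysteine and the catalog targets only cysteine).
#' @export
enumerate_forms <- function(sequence, catalog = modification_catalog(),
                            max_coalations = 1L, allow_disulfide = TRUE,
                            allow_unmodified = FALSE, start = 1L,
                            end = nchar(sequence), protein = "protein") {
  if (nrow(catalog) == 0L) stop("empty modification catalog")
  cys <- cysteine_positions(sequence)
  if (length(cys) == 0L) return(list())  # cysteine-only catalog: no forms
  states <- catalog$name[catalog$kind == "per_site"]
  if (allow_unmodified) states <- c(states, "unmodified")
  has_ss <- allow_disulfide && any(catalog$kind == "pairwise")
  forms <- list()
  add_assignments <- function(free_pos, pairs) {
    # all per-site state assignments over free_pos, honouring max_coalations
    if (length(free_pos) == 0L) {
      grids <- list(character(0))
    } else {
      g <- expand.grid(rep(list(states), length(free_pos)),
                       stringsAsFactors = FALSE)
      grids <- lapply(seq_len(nrow(g)), function(i) {
        v <- as.character(g[i, ])
        names(v) <- free_pos
        v
      })
    }
    for (v in grids) {
      if (sum(v == "CoAlation") > max_coalations) next
      forms[[length(forms) + 1L]] <<- peptide_form(
        sequence, site_states = v, disulfide_pairs = pairs,
        start = start, end = end, protein = protein, catalog = catalog
      )
    }
  }
  add_assignments(cys, list())
  if (has_ss && length(cys) >= 2L) {
    pair_idx <- utils::combn(cys, 2L, simplify = FALSE)
    for (pr in pair_idx) add_assignments(setdiff(cys, pr), list(pr))
  }
  # drop duplicates (identical label)
  labels <- vapply(forms, `[[`, character(1), "label")
  forms[!duplicated(labels)]
}

#' Match modified peptidoforms against observed precursor ions
#'
#' Emits a match for every (form, observation, charge) combination whose
#' theoretical m/z lies within `tolerance` Da of the observed m/z and
#' whose observed m/z falls inside the MS1 acquisition window. The signed
#' error is observed minus theoretical.
#'
#' @param forms List of `peptide_form` objects.
#' @param observations data.frame with columns `mz`, `charge` and
#'   optionally `intensity`.
#' @param tolerance Precursor mass tolerance in Da (on the m/z scale).
#' @param charges Candidate charge states considered (observations with a
#'   stated charge are only matched at that charge).
#' @param ms1_window Length-2 numeric MS1 m/z window; observations outside
#'   it are excluded.
#' @return data.frame with one row per match: `protein`, `start`, `end`,
#'   `label`, `modifications`, `neutral_mass`, `theoretical_mz`,
#'   `observed_mz`, `charge`, `intensity`, `error` (Da), ranked by
#'   absolute error within each observation.
#' @export
match_precursors <- function(forms, observations, tolerance = 0.5,
                             charges = 1:4, ms1_window = c(1000, 1600)) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  empty <- data.frame(protein = character(), start = integer(),
                      end = integer(), label = character(),
                      modifications = character(), neutral_mass = numeric(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      charge = integer(), intensity = numeric(),
                      error = numeric(), stringsAsFactors = FALSE)
  if (length(forms) == 0L || nrow(observations) == 0L) return(empty)
  if (any(observations$mz <= 0)) stop("observed m/z must be > 0")
  rows <- list()
  for (oi in seq_len(nrow(observations))) {
    obs <- observations[oi, ]
    if (obs$mz < ms1_window[1] || obs$mz > ms1_window[2]) next
    zs <- if (!is.null(obs$charge) && !is.na(obs$charge)) {
      as.integer(obs$charge)
    } else {
      charges
    }
    zs <- zs[zs >= 1L]
    for (f in forms) {
      for (z in zs) {
        th <- mz(f$neutral_mass, z)
        err <- obs$mz - th
        if (abs(err) <= tolerance) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein = f$protein, start = f$start, end = f$end,
            label = f$label, modifications = modification_summary(f),
            neutral_mass = f$neutral_mass, theoretical_mz = th,
            observed_mz = obs$mz, charge = z,
            intensity = if (!is.null(obs$intensity)) obs$intensity else NA_real_,
            error = err, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$observed_mz, abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

modification_summary <- function(form) {
  parts <- character(0)
  if (length(form$site_states) > 0L) {
    keep <- form$site_states != "unmodified"
    parts <- c(parts, unname(form$site_states[keep]))
  }
  if (length(form$disulfide_pairs) > 0L) {
    parts <- c(parts, rep("Disulphide", length(form$disulfide_pairs)))
  }
  if (length(parts) == 0L) "none" else paste(parts, collapse = ", ")
}

#' Identification report table
#'
#' Collapses duplicate matches and lays the result out like a published
#' identification table: annotated sequence, modification names,
#' theoretical and observed m/z, charge and signed error, sorted by span
#' start then theoretical m/z.
#'
#' @param matches data.frame from [match_precursors()].
#' @return data.frame of unique report rows.
#' @export
identification_table <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  key <- paste(matches$label, matches$charge, matches$observed_mz)
  out <- matches[!duplicated(key), , drop = FALSE]
  out <- out[order(out$start, out$theoretical_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read precursor observations from CSV
#'
#' @param path CSV with columns `mz`, `charge` and optionally `intensity`.
#' @return data.frame of observations.
#' @export
read_precursors_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("precursor CSV not found: %s", path))
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "charge")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0L) {
    stop(sprintf("precursor CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (is.null(obs$intensity)) obs$intensity <- NA_real_
  obs
}

#' Write an identification report
#'
#' @param report data.frame from [identification_table()].
#' @param tsv,json Optional output paths; either may be NULL.
#' @return Invisibly, the report.
#' @export
write_identification_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(report, json, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
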