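# Monoisotopic mass calculus and Lys-C in-silico digestion.

#' Monoisotopic residue masses and physical constants
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues
#' (i.e. amino acid minus water, as incorporated in a peptide chain),
#' the mass of water and the mass of a proton, to five decimals
#' (CODATA/IUPAC values).
#'
#' @return Named list with elements `residues` (named numeric vector of
#'   length 20), `water` and `proton` (Da).
#' @examples
#' residue_mass_table()$residues[["G"]]
#' @export
residue_mass_table <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water  = 18.010565,
    proton = 1.007276
  )
}

.mass_table <- residue_mass_table()

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus any fixed per-site mass
#' deltas (e.g. cysteine modifications).
#'
#' @param sequence Peptide sequence (single string, 20-letter alphabet).
#' @param site_deltas Optional numeric vector of mass deltas (Da); if named
#'   or accompanied by `positions`, positions are 1-based residue indices
#'   within `sequence`. Unnamed, position-free deltas are simply summed.
#' @param positions Optional integer vector of residue positions, parallel
#'   to `site_deltas`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G")                        # 75.03203
#' monoisotopic_mass("YEGQDIVSNASCTTNCLAPLAK",
#'                   site_deltas = c(57.02146, 57.02146),
#'                   positions = c(12, 16))
#' @export
monoisotopic_mass <- function(sequence, site_deltas = NULL, positions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty peptide sequence")
  bad <- which(!aa %in% names(.mass_table$residues))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  m <- sum(.mass_table$residues[aa]) + .mass_table$water
  if (!is.null(site_deltas) && length(site_deltas) > 0L) {
    if (!is.null(positions)) {
      stopifnot(length(positions) == length(site_deltas))
      if (any(positions < 1L | positions > length(aa))) {
        stop("site_delta position outside sequence")
      }
    }
    m <- m + sum(site_deltas)
  }
  m
}

#' Mass-to-charge ratio of a protonated peptide
#'
#' Standard positive-mode protonation relation
#' \eqn{m/z = (M + z \cdot m_p) / z}.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z value.
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * .mass_table$proton) / charge
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz()]: \eqn{M = z \cdot (m/z) - z \cdot m_p}.
#'
#' @param mz_value Observed m/z.
#' @param charge Positive integer charge state.
#' @return Neutral mass (Da).
#' @export
neutral_mass <- function(mz_value, charge) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  charge * mz_value - charge * .mass_table$proton
}

#' Read a protein FASTA file
#'
#' Multi-record FASTA with wrapped lines. Sequences are validated against
#' the 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aas)
  out <- data.frame(id = id, description = desc, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) validate_protein(out$sequence[i], out$id[i])
  out
}

validate_protein <- function(sequence, id = "protein") {
  if (!nzchar(sequence)) stop(sprintf("empty protein sequence in '%s'", id))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% names(.mass_table$residues))
  if (length(bad) > 0L) {
    stop(sprintf("protein '%s' has non-standard residue '%s' at position %d",
                 id, aa[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' In-silico Lys-C digestion
#'
#' Cleaves C-terminal of every lysine (including K-P bonds, Lys-C's
#' canonical specificity, unlike trypsin) and enumerates peptides with up
#' to `max_missed` internal missed cleavages. The C-terminal peptide of
#' the protein carries no cleavage requirement.
#'
#' @param sequence Protein sequence string.
#' @param max_missed Maximum internal missed cleavages (>= 0).
#' @param protein_id Identifier carried into the output.
#' @param cleave_before_proline Cleave K-P bonds (default TRUE; set FALSE
#'   for trypsin-like K-P protection).
#' @return A data.frame with columns `protein`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, ordered by start position then peptide length.
#'   Positions are 1-based and inclusive, numbered from the first residue
#'   of the supplied sequence.
#' @examples
#' digest_lysc("MAKYEGKCPK", max_missed = 1)
#' @export
digest_lysc <- function(sequence, max_missed = 1L, protein_id = "protein",
                        cleave_before_proline = TRUE) {
  if (!nzchar(sequence)) stop("empty protein")
  if (max_missed < 0) stop("max_missed must be >= 0")
  validate_protein(sequence, protein_id)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cleavage sites: positions i such that the bond after residue i is cut
  sites <- which(aa == "K")
  if (!cleave_before_proline) {
    sites <- sites[!(sites < n & aa[sites + 1L] == "P")]
  }
  sites <- sites[sites < n]            # a C-terminal K ends the protein anyway
  bounds <- c(0L, sites, n)            # fragment i spans (bounds[i]+1):bounds[i+1]
  nfrag <- length(bounds) - 1L
  rows <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        protein = protein_id, start = start, end = end,
        sequence = paste(aa[start:end], collapse = ""),
        missed_cleavages = j - i, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end - out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a digest table as TSV
#'
#' @param digest A data.frame from [digest_lysc()].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_digest_tsv <- function(digest, path) {
  utils::write.table(digest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
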