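# Shared fixtures for the test suite.

# the two published cysteine-containing Lys-C reference peptides
PEP_CYS149 <- "YEGQDIVSNASCTTNCLAPLAK"   # Cys at peptide positions 12, 16
PEP_CYS288 <- "GVLGYTEDDVVSTDFNGEVCTSVFDAK"  # Cys at peptide position 20

# deltas (exact monoisotopic Da)
D_CAM <- 57.02146
D_PA <- 71.03711
D_TRIOX <- 47.98474
D_COA <- 765.09956
D_SS <- -2.01565

# restricted four-state catalog used by the combinatorics examples
catalog_4state <- function() {
  cat <- modification_catalog()
  cat[cat$name %in% c("CAM", "PA", "trioxidation", "CoAlation", "disulphide"), ]
}

# independent brute-force digest: every substring bounded by cleavage
# points (after each K or the termini) with at most max_missed internal
# lysines not at its C-terminus
brute_digest <- function(sequence, max_missed) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cuts <- c(0L, which(aa == "K" & seq_len(n) < n), n)
  out <- list()
  for (i in seq_along(cuts)) {
    for (j in seq_along(cuts)) {
      if (cuts[j] <= cuts[i]) next
      s <- cuts[i] + 1L
      e <- cuts[j]
      pep <- aa[s:e]
      internal_k <- sum(pep[-length(pep)] == "K")
      if (internal_k <= max_missed) {
        out[[length(out) + 1L]] <- paste(pep, collapse = "")
      }
    }
  }
  sort(unlist(out))
}

# random protein sequence with controllable K content
random_protein <- function(n, seed, k_prob = 0.1) {
  set.seed(seed)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  aa <- ifelse(stats::runif(n) < k_prob, "K",
               sample(letters20, n, replace = TRUE))
  paste(aa, collapse = "")
}
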