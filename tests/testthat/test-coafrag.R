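# Fragment ladders, CoA diagnostic neutral-loss scanning, annotation and
# site localization.

test_that("loss/remnant complementarity holds for every rule entry", {
  rules <- coa_frag_rules()
  expect_length(rules$losses, 3L)
  sums <- rules$losses + rev(rules$remnants)
  expect_true(all(sums >= 764 & sums <= 766))
  expect_equal(rules$loss_variants, rules$losses - 1)
})

test_that("b/y ladder matches closed-form values and complementarity", {
  f <- peptide_form("GK")
  lad <- fragment_ladder(f)
  b1 <- lad$mz[lad$series == "b" & lad$ordinal == 1]
  y1 <- lad$mz[lad$series == "y" & lad$ordinal == 1]
  expect_equal(b1, 58.0287, tolerance = 1e-4)
  expect_equal(y1, 147.1128, tolerance = 1e-4)
  # complementarity on random peptides: b_i + y_(n-i) = M + 2 protons
  p <- residue_mass_table()$proton
  for (seed in 1:5) {
    s <- random_protein(12, seed, k_prob = 0)
    ff <- peptide_form(s)
    ll <- fragment_ladder(ff)
    n <- nchar(s)
    for (i in seq_len(n - 1)) {
      bi <- ll$mz[ll$series == "b" & ll$ordinal == i]
      yni <- ll$mz[ll$series == "y" & ll$ordinal == n - i]
      expect_equal(bi + yni, ff$neutral_mass + 2 * p, tolerance = 1e-9)
    }
  }
  expect_error(fragment_ladder(peptide_form("G")), "single-residue")
})

test_that("CoAlated ions carry full-CoA and the three remnant variants", {
  f <- peptide_form(PEP_CYS149, c("12" = "CoAlation", "16" = "CAM"))
  lad <- fragment_ladder(f)
  # y11 contains Cys16 (CAM) but not Cys12 -> single variant
  expect_equal(nrow(lad[lad$series == "y" & lad$ordinal == 6, ]), 1L)
  # b12 contains the CoAlated Cys12 -> 4 variants
  b12 <- lad[lad$series == "b" & lad$ordinal == 12, ]
  expect_setequal(b12$remnant,
                  c("fullCoA", "remnant258", "remnant338", "remnant356"))
  # remnant variants sit at +765.10/+356/+338/+258 over the unmodified ion
  f0 <- peptide_form(PEP_CYS149, c("12" = "unmodified", "16" = "CAM"))
  b12_0 <- fragment_ladder(f0)
  base <- b12_0$mz[b12_0$series == "b" & b12_0$ordinal == 12]
  shifts <- sort(b12$mz - base)
  expect_lt(max(abs(shifts - sort(c(765.09956, 258, 338, 356)))), 1)
})

test_that("disulphide rings suppress in-ring cleavages unless opened", {
  fss <- peptide_form(PEP_CYS149, disulfide_pairs = list(c(12L, 16L)))
  lad <- fragment_ladder(fss)
  # bonds 12..15 are inside the ring: no b12..b15, no y7..y10
  expect_false(any(lad$series == "b" & lad$ordinal %in% 12:15))
  n <- nchar(PEP_CYS149)
  expect_false(any(lad$series == "y" & lad$ordinal %in% (n - 15):(n - 12)))
  lad_open <- fragment_ladder(fss, ring_open = TRUE)
  expect_true(any(lad_open$series == "b" & lad_open$ordinal == 13))
})

test_that("diagnostic scan finds the three losses at the published positions", {
  # 3+ precursor at 1040.765 with same-charge loss peaks at
  # precursor - {410, 428, 508}/3
  prec <- 1040.765
  losses <- c(410, 428, 508)
  peaks <- prec - losses / 3
  sp <- ms2_spectrum(prec, 3L, peaks, rep(100, 3))
  sc <- diagnostic_scan(sp)
  expect_true(sc$verdict)
  expect_equal(sc$n_losses_matched, 3L)
  expect_equal(sort(unique(sc$hits$loss)), losses)
  # expected positions arithmetic: scanner searched exactly prec - L/3
  hit3 <- sc$hits[sc$hits$charge == 3L & sc$hits$variant %in% losses, ]
  expect_equal(sort(hit3$expected_mz), sort(prec - losses / 3),
               tolerance = 1e-9)

  # no loss peaks -> negative verdict
  sp0 <- ms2_spectrum(prec, 3L, c(300, 500, 700), rep(100, 3))
  sc0 <- diagnostic_scan(sp0)
  expect_false(sc0$verdict)
  expect_equal(sc0$n_losses_matched, 0L)

  # hydrogen-shift variant only (-409/3), min_losses 1
  spv <- ms2_spectrum(prec, 3L, prec - 409 / 3, 100)
  scv <- diagnostic_scan(spv, min_losses = 1L)
  expect_true(scv$verdict)
  expect_true(409 %in% scv$hits$variant)
  expect_equal(unique(scv$hits$loss), 410)

  expect_error(diagnostic_scan(ms2_spectrum(prec, NA, 1, 1)),
               "precursor charge")
})

test_that("diagnostic scan is monotone in tolerance and intensity threshold", {
  prec <- 1040.765
  peaks <- prec - c(410, 428, 508) / 3 + c(0.3, 0.6, 0.9)
  sp <- ms2_spectrum(prec, 3L, c(peaks, 500), c(100, 50, 3, 1000))
  n_at <- function(tol, rel) {
    diagnostic_scan(sp, tolerance = tol,
                    min_rel_intensity = rel)$n_losses_matched
  }
  expect_lte(n_at(0.4, 0.05), n_at(1.0, 0.05))
  expect_lte(n_at(1.0, 0.2), n_at(1.0, 0.01))
  # the 3-intensity peak (0.3% of base) is dropped at the 5% default
  expect_equal(n_at(1.0, 0.05), 2L)
  expect_equal(n_at(1.0, 0.001), 3L)
})

test_that("self-annotation of noiseless synthetic spectra reaches coverage 1", {
  for (seed in 1:5) {
    len <- sample(5:25, 1)
    s <- random_protein(len, seed, k_prob = 0)
    cys <- cysteine_positions(s)
    states <- if (length(cys) > 0) {
      stats::setNames(rep("CAM", length(cys)), cys)
    } else {
      character()
    }
    f <- peptide_form(s, states)
    sp <- simulate_ms2(f, precursor_charge = 2L, include_losses = FALSE,
                       seed = seed)
    ann <- annotate_spectrum(sp, f)
    expect_equal(ann$coverage, 1.0)
  }
})

test_that("annotation drops with a wrong-mass form and zero tolerance", {
  f <- peptide_form(PEP_CYS149, c("12" = "CoAlation", "16" = "CAM"))
  sp <- simulate_ms2(f, seed = 7)
  wrong <- peptide_form(PEP_CYS149, c("12" = "CAM", "16" = "CAM"))
  expect_warning(ann_wrong <- annotate_spectrum(sp, wrong), "differs")
  ann_right <- annotate_spectrum(sp, f)
  expect_lt(ann_wrong$coverage, ann_right$coverage)
  # jittered peaks at tolerance 0 match nothing
  spj <- simulate_ms2(f, mz_jitter_sd = 0.01, seed = 8)
  annj <- annotate_spectrum(spj, f, tolerance = 0)
  expect_equal(annj$coverage, 0)
  # empty spectrum: coverage 0, no error
  empty <- ms2_spectrum(mz(f$neutral_mass, 3), 3L, numeric(0), numeric(0))
  expect_equal(annotate_spectrum(empty, f)$coverage, 0)
})

test_that("site localization recovers the generating site and flags ties", {
  cand <- list(
    peptide_form(PEP_CYS149, c("12" = "CoAlation", "16" = "CAM")),
    peptide_form(PEP_CYS149, c("12" = "CAM", "16" = "CoAlation"))
  )
  for (truth in 1:2) {
    sp <- simulate_ms2(cand[[truth]], include_losses = FALSE, seed = truth)
    loc <- localize_site(sp, cand)
    expect_false(loc$tie)
    expect_equal(loc$best$label, cand[[truth]]$label)
  }
  # spectrum with no site-determining ions -> tie
  sp_empty <- ms2_spectrum(mz(cand[[1]]$neutral_mass, 3), 3L,
                           numeric(0), numeric(0))
  loc0 <- localize_site(sp_empty, cand)
  expect_true(loc0$tie)
  expect_null(loc0$best)
  expect_error(localize_site(sp_empty, cand[1]), "nothing to localize")
  # candidates must be mass permutations
  other <- peptide_form(PEP_CYS149, c("12" = "CAM", "16" = "CAM"))
  expect_error(localize_site(sp_empty, list(cand[[1]], other)),
               "equal total mass")
})

test_that("localization succeeds on all noiseless spectra with determining ions", {
  cand <- list(
    peptide_form("ACDEFGCK", c("2" = "CoAlation", "7" = "CAM")),
    peptide_form("ACDEFGCK", c("2" = "CAM", "7" = "CoAlation"))
  )
  hits <- 0L
  for (seed in 1:10) {
    truth <- (seed %% 2) + 1L
    sp <- simulate_ms2(cand[[truth]], include_losses = FALSE, seed = seed)
    loc <- localize_site(sp, cand)
    if (!loc$tie && identical(loc$best$label, cand[[truth]]$label)) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 10L)
})

test_that("MGF files round-trip through the reader and writer", {
  f <- peptide_form(PEP_CYS149, c("12" = "CoAlation", "16" = "CAM"))
  sp <- simulate_ms2(f, n_noise_peaks = 5, mz_jitter_sd = 0.002, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, tmp)
  back <- read_mgf(tmp)
  expect_length(back, 1L)
  expect_equal(back[[1]]$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  expect_equal(back[[1]]$precursor_charge, sp$precursor_charge)
  expect_equal(back[[1]]$peaks$mz, sp$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$intensity, sp$peaks$intensity,
               tolerance = 1e-6)
})
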