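#!/usr/bin/env Rscript
# Inactivation kinetics: two-stage recovery of the apparent second-order
# rate constants for CoASSCoA-like and GSSG-like series, half-time tables
# and DTT-recovery percentages.

suppressMessages(library(coalscan))
dir.create("results", showWarnings = FALSE)

series <- list(
  CoASSCoA = list(k2 = 3.0, concs = c(250, 500, 750, 1000) * 1e-6),
  GSSG = list(k2 = 0.34, concs = c(2.5, 5.0, 7.5, 10) * 1e-3)
)

rows <- list()
for (nm in names(series)) {
  s <- series[[nm]]
  tc <- simulate_timecourses(s$k2, s$concs, seed = 1)
  fit <- fit_inactivation_series(tc)
  cat(sprintf("%s: generator k2 = %.3g, recovered k2 = %.6g 1/(M s)\n",
              nm, s$k2, fit$second_order$k2))
  per <- fit$per_concentration
  per$reagent <- nm
  per$t_half_min <- per$t_half / 60
  rows[[nm]] <- per
  # noisy replicate spread (3% activity noise, 100 seeds)
  k2s <- vapply(1:100, function(i) {
    d <- simulate_timecourses(s$k2, s$concs, noise_sd = 0.03, seed = 100 + i)
    fit_inactivation_series(d)$second_order$k2
  }, numeric(1))
  cat(sprintf("  with 3%% noise over 100 seeds: mean %.4g, sd %.2g\n",
              mean(k2s), sd(k2s)))
}
per_all <- do.call(rbind, rows)
write.csv(per_all, "results/inactivation_kinetics.csv", row.names = FALSE)

cat("\nModel half-times at the highest concentrations (ln2 / k_obs):\n")
print(per_all[per_all$concentration_M %in% c(1e-3, 1e-2),
              c("reagent", "concentration_M", "k_obs", "t_half_min")],
      digits = 4)
cat("note: published half-times read directly from inactivation curves\n",
    "(1.07 min at 1 mM CoASSCoA, 3.45 min at 10 mM GSSG) are steeper than\n",
    "single-exponential ln2/k_obs values; both conventions are reported.\n")

cat("\nDTT recovery of constructed inactivation endpoints:\n")
rec <- data.frame(
  condition = c("H2O2 0.1 mM", "H2O2 1 mM", "H2O2 0.1 mM + CoA",
                "H2O2 1 mM + CoA"),
  recovered_pct = c(recovery_percent(32, 100), recovery_percent(12, 100),
                    recovery_percent(93, 100), recovery_percent(81, 100))
)
print(rec)
write.csv(rec, "results/dtt_recovery.csv", row.names = FALSE)
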