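# Activity computation, inactivation kinetics and Michaelis-Menten fits.

test_that("absorbance-to-units conversion follows Beer-Lambert", {
  expect_equal(activity_from_absorbance(0.6220, volume_L = 1e-3)$units, 0.1)
  expect_equal(activity_from_absorbance(0, volume_L = 1e-3)$units, 0)
  # published specific activity from constructed inputs: 14.56 U on 0.1 mg
  sa <- activity_from_absorbance(14.56 * 6220 / 1e6 / 1e-3, volume_L = 1e-3,
                                 enzyme_mg = 0.1)
  expect_equal(sa$units, 14.56, tolerance = 1e-9)
  expect_equal(sa$specific_activity, 145.6, tolerance = 1e-9)
  expect_error(activity_from_absorbance(0.1, volume_L = 1e-3, enzyme_mg = 0),
               "> 0")
  expect_error(activity_from_absorbance(-1, volume_L = 1e-3), ">= 0")
})

test_that("noiseless exponential decay is recovered exactly", {
  t <- seq(0, 1200, 60)
  k_true <- 3.0e-3
  f <- fit_inactivation(t, 100 * exp(-k_true * t))
  expect_equal(f$k_obs, k_true, tolerance = 1e-6)
  expect_equal(f$A0, 100, tolerance = 1e-4)
  # t_half identity holds exactly for every fit
  expect_equal(f$t_half * f$k_obs, log(2), tolerance = 1e-9)
  # non-decreasing activity -> k = 0 with warning
  expect_warning(f0 <- fit_inactivation(t[1:5], c(100, 100, 101, 102, 103)),
                 "does not decrease")
  expect_equal(f0$k_obs, 0)
  expect_error(fit_inactivation(c(0, 60), c(100, 50)), "at least 3")
  expect_error(fit_inactivation(c(0, 60, 30), c(100, 80, 50)),
               "strictly increasing")
})

test_that("noisy k_obs recovery stays within 10% of generator truth", {
  t <- seq(0, 1200, 60)
  k_true <- 3.0e-3
  set.seed(11)
  a <- pmax(100 * exp(-k_true * t) * (1 + rnorm(length(t), 0, 0.03)), 0)
  f <- fit_inactivation(t, a)
  expect_equal(f$k_obs, k_true, tolerance = 0.1)
})

test_that("interpolated and model half-times agree on exponential data", {
  t <- seq(0, 1200, 30)
  k <- 2e-3
  f <- fit_inactivation(t, 100 * exp(-k * t))
  expect_equal(f$t_half_interpolated, log(2) / k, tolerance = 0.02 * f$t_half)
})

test_that("second-order fit is the identity on fit-forward data", {
  expect_equal(fit_second_order(c(1, 2, 3) * 1e-3,
                                3.0 * c(1, 2, 3) * 1e-3)$k2, 3.0,
               tolerance = 1e-9)
  for (k2_true in c(0.05, 0.34, 3.0, 40)) {
    tc <- simulate_timecourses(k2_true, c(0.5, 1, 2, 4) * 1e-3)
    fit <- fit_inactivation_series(tc)
    expect_equal(fit$second_order$k2, k2_true, tolerance = 1e-4 * k2_true)
  }
  expect_error(fit_second_order(c(0, 0), c(1, 2)), "zero")
  expect_error(fit_second_order(1e-3, 1), "at least 2")
})

test_that("the published second-order constants are recovered end to end", {
  # GSSG-like series: 2.5-10 mM, generator truth 0.34 1/(M s)
  gssg <- simulate_timecourses(0.34, c(2.5, 5, 7.5, 10) * 1e-3)
  expect_equal(fit_inactivation_series(gssg)$second_order$k2, 0.34,
               tolerance = 1e-4)
  # CoASSCoA-like series: 250-1000 uM, generator truth 3.0 1/(M s)
  coa <- simulate_timecourses(3.0, c(250, 500, 750, 1000) * 1e-6)
  expect_equal(fit_inactivation_series(coa)$second_order$k2, 3.0,
               tolerance = 1e-3)
})

test_that("recovery percentages reproduce the published values", {
  expect_equal(recovery_percent(5, 5), 100)
  # H2O2 only: DTT recovers 32% and 12%
  expect_equal(recovery_percent(32, 100), 32)
  expect_equal(recovery_percent(12, 100), 12)
  # H2O2 + CoA: 93% and 81%
  expect_equal(recovery_percent(93, 100), 93)
  expect_equal(recovery_percent(0.81 * 145.6, 145.6), 81)
  expect_error(recovery_percent(10, 0), "> 0")
})

test_that("Michaelis-Menten fit recovers parameters and kcat conventions", {
  d <- simulate_mm(Vmax = 152, Km_mM = 1.23)
  f <- fit_mm(d$substrate_mM, d$rate_U_per_mg)
  expect_equal(f$Vmax, 152, tolerance = 1e-6)
  expect_equal(f$Km, 1.23, tolerance = 1e-6)
  # rate at S = Km equals Vmax/2 on the fitted curve
  expect_equal(f$Vmax * f$Km / (f$Km + f$Km), f$Vmax / 2)
  # tetramer convention reproduces the published ~360 1/s
  expect_lt(abs(f$kcat - 358), 1)
  expect_lt(abs(f$kcat - 360), 18)  # within the printed error
  # exact recovery over 2 decades of random parameters
  for (seed in 1:5) {
    set.seed(seed)
    v <- runif(1, 15, 1500)
    km <- 10^runif(1, -1, 1)
    grid <- km * c(0.1, 0.3, 0.7, 1, 2, 5, 10)
    dd <- simulate_mm(v, km, substrate_mM = grid)
    ff <- fit_mm(dd$substrate_mM, dd$rate_U_per_mg)
    expect_equal(ff$Vmax, v, tolerance = 1e-5 * v)
    expect_equal(ff$Km, km, tolerance = 1e-5 * km)
  }
  expect_error(fit_mm(c(1, 2, 3, 4), c(0, 0, 0, 0)), "no positive rates")
})

test_that("kcat/Km ratios recomputed from published entries match 2 sig figs", {
  sig2 <- function(x) signif(x, 2)
  # G3P: Vmax 152, Km 1.23 mM -> 2.9e5; NAD+: 152, 0.12 -> 3.0e6;
  # Pi: 149, 3.65 -> 9.6e4 (all with the tetramer mass convention)
  expect_equal(sig2(kcat_from_vmax(152) / (1.23e-3)), 2.9e5)
  expect_equal(sig2(kcat_from_vmax(152) / (0.12e-3)), 3.0e6)
  expect_equal(sig2(kcat_from_vmax(149) / (3.65e-3)), 9.6e4)
})
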