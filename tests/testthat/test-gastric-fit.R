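test_that("timecourse validates its invariants", {
  expect_error(timecourse(c(0, 30, 30), c(1, 2, 3)), "duplicate time")
  expect_error(timecourse(c(0, 60, 30), c(1, 2, 3)), "increasing")
  expect_error(timecourse(c(0, 30), c(1, -2)), ">= 0")
  tc <- timecourse(c(0, 30, 60), c(0, 1, 2), "glucose")
  expect_identical(attr(tc, "analyte"), "glucose")
})

test_that("classify_z applies the slope rule with inclusive bounds", {
  # slopes +0.06, 0.00, -0.06 -> fast, slow, off
  tc <- timecourse(c(0, 30, 60, 90), c(0, 1.8, 1.8, 0))
  expect_identical(z_codes(classify_z(tc)), c(2L, 1L, 0L))
  # slopes exactly at +/- threshold are slow (inclusive)
  tc2 <- timecourse(c(0, 30, 60), c(1.5, 3.0, 1.5))
  expect_identical(z_codes(classify_z(tc2)), c(1L, 1L))
  # just beyond the threshold tips the classification
  tc3 <- timecourse(c(0, 30, 60), c(1.5, 3.1, 1.4))
  expect_identical(z_codes(classify_z(tc3)), c(2L, 0L))
  # constant concentration is all slow
  tc4 <- timecourse(c(0, 30, 60), c(2, 2, 2))
  expect_identical(z_codes(classify_z(tc4)), c(1L, 1L))
  expect_error(classify_z(tc4, threshold = 0), "> 0")
})

test_that("ac_analytic reproduces hand-computed closed forms", {
  p <- ref_fix$params
  # pure elimination interval: no stomach input
  p0 <- update_parameters(p, iAc_S = 0, iAc_P = 100)
  z0 <- z_schedule(c(0, 30), 0L)
  expect_equal(ac_analytic(p0, z0, 30) * (0.9 * 60), 100 * exp(-0.066),
               tolerance = 1e-12)
  # first reference interval (fast): chained masses at 30 min
  z <- ref_fix$z
  c30 <- ac_analytic(p, z, 30)
  AcS30 <- 3234 * exp(-0.003 * 30)
  expect_equal(AcS30, 2955.7, tolerance = 1e-4)
  AcP30 <- 0.003 * 3234 * (exp(-0.003 * 30) - exp(-0.0022 * 30)) /
    (0.0022 - 0.003)
  expect_equal(c30, AcP30 / (0.9 * 60), tolerance = 1e-12)
  expect_equal(c30, 4.99, tolerance = 1e-2)
  # zero dose leaves pure basal elimination at all times
  tts <- c(0, 10, 100, 420)
  expect_equal(ac_analytic(p0, ref_fix$z, tts),
               100 * exp(-0.0022 * tts) / (0.9 * 60), tolerance = 1e-12)
})

test_that("degenerate k == k_u interval uses the continuous limit", {
  p <- update_parameters(ref_fix$params, k_SP2 = 0.0022, k_SP3 = 0.0022,
                         k_Ac_UAc = 0.0022)
  z <- z_schedule(c(0, 60), 1L)
  got <- ac_analytic(p, z, c(30, 60)) * (0.9 * 60)
  want <- 0.0022 * 3234 * c(30, 60) * exp(-0.0022 * c(30, 60))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic solution matches the RK4 integrator on random instances", {
  set.seed(7)
  for (i in 1:5) {
    inst <- random_ac_instance()
    traj <- simulate_gi(inst$params, inst$z, dt = 0.002, report_every = 30)
    pred <- ac_analytic(inst$params, inst$z, traj$time_min)
    expect_equal(pred, traj$cAcP_mg_per_L,
                 tolerance = 1e-8)
  }
})

test_that("rmspe matches hand arithmetic and rejects a zero mean", {
  expect_identical(rmspe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmspe(c(1, 3), c(2, 2)), 50)
  expect_equal(rmspe(c(0, 0, 0), c(1, 1, 1)), 100)
  expect_error(rmspe(c(1, 2), c(1, -1)), "zero")
  expect_error(rmspe(1, c(1, 2)), "lengths differ")
})

test_that("fit_ac recovers known parameters from noise-free data", {
  p <- ref_fix$params
  times <- c(seq(0, 240, by = 30), 300, 360, 420)
  tc <- timecourse(times, ac_analytic(p, ref_fix$z, times), "acetaminophen")
  fit <- fit_ac(tc, ref_fix$z, mode = "two_rate", params = p)
  expect_equal(fit$k_SP2, 0.0015, tolerance = 1e-6)
  expect_equal(fit$k_SP3, 0.003, tolerance = 1e-6)
  expect_equal(fit$k_Ac_UAc, 0.0022, tolerance = 1e-6)
  expect_lt(fit$rmspe_pct, 1e-4)
})

test_that("two-rate fit never scores worse than the nested one-rate fit", {
  set.seed(11)
  inst <- random_ac_instance()
  times <- c(seq(0, 240, by = 30), 300, 360, 420)
  clean <- ac_analytic(inst$params, inst$z, times)
  noisy <- clean * exp(rnorm(length(clean), 0, 0.08))
  tc <- timecourse(times, noisy, "acetaminophen")
  z <- classify_z(tc)
  f1 <- fit_ac(tc, z, mode = "one_rate", params = inst$params)
  f2 <- fit_ac(tc, z, mode = "two_rate", params = inst$params)
  expect_lte(f2$rss, f1$rss + 1e-10)
  expect_lte(f2$rmspe_pct, f1$rmspe_pct + 1e-8)
  expect_lte(f2$k_SP2, f2$k_SP3)
})

test_that("one-rate mode collapses the schedule to on/off", {
  tc <- timecourse(c(0, 30, 60, 90), c(0, 1.8, 1.8, 0))
  f <- fit_ac(tc, mode = "one_rate")
  expect_identical(z_codes(f$z), c(1L, 1L, 0L))
  expect_equal(f$k_SP2, f$k_SP3)
})

test_that("fit objective is locally optimal at the truth on clean data", {
  p <- ref_fix$params
  times <- seq(0, 420, by = 30)
  obs <- ac_analytic(p, ref_fix$z, times)
  sse <- function(k2, k3, ku) {
    pr <- ac_analytic(update_parameters(p, k_SP2 = k2, k_SP3 = k3,
                                        k_Ac_UAc = ku), ref_fix$z, times)
    sum((pr - obs)^2)
  }
  base <- sse(0.0015, 0.003, 0.0022)
  for (d in c(-1e-4, 1e-4)) {
    expect_gte(sse(0.0015 + d, 0.003, 0.0022), base)
    expect_gte(sse(0.0015, 0.003 + d, 0.0022), base)
    expect_gte(sse(0.0015, 0.003, 0.0022 + d), base)
  }
})
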