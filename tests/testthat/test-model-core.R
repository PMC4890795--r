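test_that("emptying_rate maps codes to the reference rate constants", {
  p <- ref_fix$params
  expect_identical(emptying_rate(0L, p), 0)
  expect_equal(emptying_rate(1L, p), 0.0015)
  expect_equal(emptying_rate(2L, p), 0.003)
  expect_equal(emptying_rate(c(2L, 0L, 1L), p), c(0.003, 0, 0.0015))
  expect_error(emptying_rate(3L, p), "interval 1")
  expect_error(emptying_rate(c(1L, 5L), p), "interval 2")
})

test_that("concentrations divide masses by the fixed distribution volumes", {
  p <- ref_fix$params
  st <- model_state(Ac_P = 0, Gl_P = 90, In_P = 5.92)
  cc <- concentrations(st, p)
  expect_identical(cc$cAc_P, 0)
  expect_equal(cc$cGl_P, 90 / (0.251 * 60), tolerance = 1e-12)
  expect_equal(cc$cGl_P, 5.976, tolerance = 1e-4)
  # basal insulin concentration reproduces the tabulated basal signal
  expect_equal(cc$cIn_P, 0.393, tolerance = 1e-3)
})

test_that("fluxes at the basal reference state match closed-form arithmetic", {
  p <- ref_fix$params
  st <- initial_state(p)
  cc <- concentrations(st, p)
  fl <- model_fluxes(st, 0L, lagged_PGl_ex = 0, lagged_cIn_P = p$iIs, p)
  # Hill secretion: 10 / (1 + (8.8/5.976)^9)
  expect_equal(fl$PIn, 10 / (1 + (8.8 / cc$cGl_P)^9), tolerance = 1e-12)
  expect_equal(fl$PIn, 0.298, tolerance = 1e-3)
  # glucose utilization balances tabulated endogenous production
  expect_equal(fl$UGl, 8.7e-7 * cc$cGl_P + 0.0757 * 0.393 * cc$cGl_P,
               tolerance = 1e-12)
  expect_equal(round(fl$UGl, 3), 0.178)
  expect_equal(fl$PGl_end, p$iPGl_end)
  # no outflow: stomach derivatives vanish
  expect_identical(fl$dAcS, 0)
  expect_identical(fl$dGlS, 0)
  # outflow code selects the stomach drain
  fl2 <- model_fluxes(st, 2L, 0, p$iIs, p)
  expect_equal(fl2$dAcS, -0.003 * p$iAc_S)
  expect_equal(fl2$dGlS, -0.003 * p$iGl_S)
})

test_that("Hill secretion is continuous at 0, monotone and bounded", {
  p <- ref_fix$params
  expect_identical(insulin_secretion(0, p), 0)
  expect_identical(insulin_secretion(-1, p), 0)
  cg <- seq(0.1, 40, by = 0.1)
  pin <- insulin_secretion(cg, p)
  expect_true(all(diff(pin) > 0))
  expect_true(all(pin < p$V_PIn))
})

test_that("steady-state k_In_UIn follows the basal insulin balance", {
  p <- ref_fix$params
  k <- steady_state_k_in_uin(p)
  expect_equal(k, 0.758, tolerance = 1e-3)
  # linear in V_PIn
  expect_equal(steady_state_k_in_uin(update_parameters(p, V_PIn = 20)),
               2 * k, tolerance = 1e-12)
  # K -> 0 limit: Hill factor -> 1
  p0 <- update_parameters(p, K_Gl_PIn = 1e-12)
  expect_equal(steady_state_k_in_uin(p0),
               p$V_PIn / (p$iIn_P / (0.251 * 60)), tolerance = 1e-9)
  expect_error(steady_state_k_in_uin(update_parameters(p, iIn_P = 0)),
               "iIn_P")
})

test_that("steady-state iPGl_end reproduces the tabulated production", {
  p <- ref_fix$params
  v <- steady_state_ipgl_end(p)
  expect_equal(round(v, 3), 0.178)
  expect_identical(steady_state_ipgl_end(
    update_parameters(p, k_Gl_UGl = 0, k_Is_UGl = 0)), 0)
  # linear in iGl_P
  expect_equal(steady_state_ipgl_end(update_parameters(p, iGl_P = 180)),
               2 * v, tolerance = 1e-12)
})

test_that("parameter validation enforces the type invariants", {
  expect_error(model_parameters(BW = 0), "BW")
  expect_error(model_parameters(BW = 60, k_SP2 = 0.01, k_SP3 = 0.001),
               "k_SP3")
  expect_error(model_parameters(BW = 60, exp_PIn = 0.5), "exp_PIn")
  expect_error(model_parameters(BW = 60, K_Gl_PIn = 0), "K_Gl_PIn")
  expect_error(model_parameters(BW = 60, iGl_S = -1), ">= 0")
  expect_error(update_parameters(ref_fix$params, nope = 1),
               "valid symbols")
  expect_error(model_state(Gl_P = -1), ">= 0")
})

test_that("parameter sets round-trip through the flat config format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_parameters(ref_fix$params, path)
  back <- read_parameters(path)
  expect_equal(unclass(back), unclass(ref_fix$params), tolerance = 1e-15)
  writeLines(c("BW = 60", "bogus = 1"), path)
  expect_error(read_parameters(path), "bogus")
})

test_that("z_schedule validates structure and looks up half-open intervals", {
  z <- ref_fix$z
  expect_length(z$breakpoints, 15)
  expect_length(z$values, 14)
  # code switches exactly at the breakpoint (right-hand interval wins)
  expect_identical(z_code_at(z, c(0, 29.999, 30, 59.999)),
                   c(2L, 2L, 1L, 1L))
  # beyond the last breakpoint the last code applies
  expect_identical(z_code_at(z, 1e6), 0L)
  expect_error(z_schedule(c(0, 30, 30), c(1, 1)), "increasing")
  expect_error(z_schedule(c(0, 30), c(3)), "interval 1")
  expect_error(z_schedule(c(5, 30), c(1)), "start at 0")
  expect_error(z_schedule(c(0, 30, 60), c(1)), "breakpoints")
})
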