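test_that("enzyme state stays at 1 without ritonavir and hits the ODE fixed point", {
  p <- ddi_params()
  tt <- seq(0, 120, by = 12)
  tr <- enzyme_trajectory(p, numeric(0), tt)
  expect_equal(tr$e_gut, rep(1, length(tt)))

  # continuous presence drives E to k_deg / (k_deg + k_inact)
  rito <- dose_events(seq(0, 2000, by = 12), "ritonavir", 1e8)
  tr <- enzyme_trajectory(p, rito, c(1500, 2000))
  expect_equal(tr$e_gut, rep(p$k_deg / (p$k_deg + p$k_inact), 2),
               tolerance = 1e-8)
  expect_true(all(tr$e_gut > 0 & tr$e_gut <= 1))
})

test_that("enzyme recovery after discontinuation follows the closed form", {
  p <- ddi_params()
  rito <- dose_events(seq(0, 48, by = 12), "ritonavir", 1e8)  # stops at 60 h
  t0 <- 60
  e0 <- enzyme_trajectory(p, rito, t0)$e_gut
  tt <- seq(60, 300, by = 10)
  tr <- enzyme_trajectory(p, rito, tt)
  expected <- 1 - (1 - e0) * exp(-p$k_deg * (tt - t0))
  expect_equal(tr$e_gut, expected, tolerance = 1e-6)
  expect_true(all(diff(tr$e_gut) > 0))       # monotone recovery
  expect_lt(abs(tr$e_gut[length(tt)] - 1), 0.01)
})

test_that("enzyme trajectory matches an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- ddi_params(k_deg = 0.05, k_inact = 0.4)
  rt <- seq(0, 108, by = 12)
  iv <- cbind(rt, rt + p$rito_coverage_h)
  # collapse overlapping intervals to one block per contiguous run
  tt <- sort(c(seq(1, 240, by = 7), 96, 120.5))
  ours <- enzyme_trajectory(p, dose_events(rt, "ritonavir", 1e8), tt)$e_gut
  oracle <- oracle_enzyme_desolve(tt, p$k_deg, p$k_inact, iv)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("plasma model equals the numerical integrator without ritonavir", {
  skip_if_not_installed("deSolve")
  p <- ddi_params()
  statin <- dose_events(0, "statin", 1e7)
  tt <- trial_sampling_times()[-1]
  ours <- simulate_concentrations(p, statin, NULL, tt)
  oracle <- oracle_2cpt_zo_desolve(tt, 1e7 * p$f_rel_base, p$d0,
                                   p$cl_f_base, p$vc_f, p$q_f, p$vp_f)
  expect_equal(ours, oracle, tolerance = 1e-6)

  expect_equal(simulate_concentrations(p, NULL, NULL, tt), rep(0, length(tt)))
})

test_that("doses superpose linearly", {
  p <- ddi_params()
  rito <- ritonavir_bid_day5()
  tt <- seq(0, 72, by = 0.5)
  two <- simulate_concentrations(p, dose_events(c(0, 24), "statin",
                                                c(1e7, 1e7)), rito, tt)
  one_a <- simulate_concentrations(p, dose_events(0, "statin", 1e7), rito, tt)
  one_b <- simulate_concentrations(p, dose_events(24, "statin", 1e7), rito, tt)
  expect_equal(two, one_a + one_b, tolerance = 1e-8)
})

test_that("baseline mass balance: AUCinf x CL/F = F x dose", {
  p <- ddi_params()
  statin <- dose_events(0, "statin", 1e7)
  f <- function(t) simulate_concentrations(p, statin, NULL, t)
  auc_0_200 <- oracle_dense_auc(f, 0, 200, dt = 0.01)
  # close the integral with the analytic terminal tail
  lam <- disposition_eigenvalues(p)[["beta"]]
  auc_inf <- auc_0_200 + f(200) / lam
  # AUC (h*ng/mL) x CL (L/h -> mL/h / 1000) = dose (ng) x F
  expect_equal(auc_inf * p$cl_f_base * 1000, 1e7 * p$f_rel_base,
               tolerance = 1e-4)
})

test_that("simulated terminal half-life matches the slow eigenvalue", {
  p <- ddi_params()
  statin <- dose_events(0, "statin", 1e7)
  tt <- c(0.5, 1, 2, 24, 48, 72, 96)
  prof <- make_profile(tt, simulate_concentrations(p, statin, NULL, tt))
  lz <- fit_lambda_z(prof)
  beta <- disposition_eigenvalues(p)[["beta"]]
  expect_lt(abs(lz$lambda_z / beta - 1), 0.02)
})

test_that("full gut inhibition reproduces the fitted modulation factors", {
  # k_inact >> k_deg makes E_gut ~ 0 at the day-5 dose
  p <- ddi_params(k_inact = 1000)
  statin <- dose_events(0, "statin", 1e7)
  rito <- ritonavir_bid_day5()
  f_base <- function(t) simulate_concentrations(p, statin, NULL, t)
  f_day5 <- function(t) simulate_concentrations(p, statin, rito, t)
  lam <- disposition_eigenvalues(p)[["beta"]]
  auc <- function(f) oracle_dense_auc(f, 0, 300, dt = 0.01) + f(300) / lam
  # bioavailability-only ceiling: AUC ratio 1/theta_f = 1/0.57
  expect_equal(auc(f_day5) / auc(f_base), 1 / p$theta_f, tolerance = 1e-3)

  # absorption-duration prolongation: peak time ratio equals theta_d
  grid <- seq(0.01, 6, by = 0.001)
  tmax_base <- grid[which.max(f_base(grid))]
  tmax_day5 <- grid[which.max(f_day5(grid))]
  expect_equal(tmax_base, p$d0, tolerance = 0.01)
  expect_equal(tmax_day5 / tmax_base, p$theta_d, tolerance = 0.01)
})

test_that("day-5 exposure ratio is unity without inactivation", {
  p <- ddi_params(k_inact = 0)
  r <- day5_exposure_ratio(p)
  expect_equal(r$auc_ratio, 1, tolerance = 1e-6)
  expect_equal(r$cmax_ratio, 1, tolerance = 1e-6)

  # with near-complete inhibition the NCA ratio approaches the 1.75 ceiling
  r2 <- day5_exposure_ratio(ddi_params(k_inact = 1000))
  expect_equal(r2$auc_ratio, 1 / 0.57, tolerance = 0.05)
  expect_gt(r2$auc_ratio, 1.6)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(ddi_params(theta_f = 1.2), "theta_f")
  expect_error(ddi_params(theta_d = 0.9), "theta_d")
  expect_error(ddi_params(k_deg = 0), "k_deg")
  expect_error(ddi_params(k_inact = -1), "k_inact")
})
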