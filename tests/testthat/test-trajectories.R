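test_that("time rescaling follows tau = 2*mu*t/30", {
  expect_identical(rescale_time(0, 3e-4), 0)
  expect_equal(rescale_time(30 / (2 * 3e-4), 3e-4), 1)
  t <- c(0, 10, 5e4, 1e6)
  expect_equal(unscale_time(rescale_time(t, 2e-4), 2e-4), t, tolerance = 1e-12)
  expect_error(rescale_time(10, 0))
})

test_that("the optimum is a fixed point and trajectories start at init", {
  p <- headline_params()
  tr <- solve_expected(p, init = c(0, 0))
  expect_true(all(tr$z_m == 0) && all(tr$z_f == 0))
  tr2 <- solve_expected(p)
  expect_equal(c(tr2$z_m[1], tr2$z_f[1]), c(-1, 0))
  expect_true(all(diff(tr2$tau) > 0))
  expect_equal(nrow(tr2), length(tr2$t))
})

test_that("rho = 0 decouples the sexes with the printed exponential rate", {
  p <- headline_params(S_m = 1, S_f = 0.4, rho = 0)
  tr <- solve_expected(p)
  expect_equal(tr$z_f, rep(0, nrow(tr)), tolerance = 1e-12)
  # heterogametic sex relaxes at rate 10*sigma2*Ne*S_m (= Ne*S_m at sigma2=0.1)
  rate <- 10 * p$sigma2 * p$Ne * p$S_m
  expect_equal(tr$z_m, -p$z0 * exp(-rate * tr$tau), tolerance = 1e-9)
})

test_that("closed form matches adaptive numeric integration", {
  for (sys in c("XY", "ZW")) {
    p <- headline_params(sys, S_m = 1, S_f = 0.1, rho = 0.8)
    grid <- seq(0, 0.05, length.out = 101)
    a <- solve_expected(p, tau_grid = grid, method = "closed_form")
    b <- solve_expected(p, tau_grid = grid, method = "numeric")
    expect_lt(max(abs(a$z_m - b$z_m), abs(a$z_f - b$z_f)), 1e-6)
  }
  # variants refuse the closed form
  expect_error(solve_expected(headline_params(dominance = "dominant")),
               "closed_form")
  expect_error(solve_expected(headline_params(degradation = "gradual")),
               "closed_form")
})

test_that("baseline trajectories converge to complete dosage compensation", {
  for (rho in c(-0.5, 0, 0.5, 0.9)) {
    p <- headline_params(S_m = 0.7, S_f = 0.3, rho = rho)
    tr <- solve_expected(p, tau_grid = seq(0, 30 / (10 * p$sigma2 * p$Ne *
                                                      min(p$S_m, p$S_f) *
                                                      0.05), length.out = 50))
    expect_lt(abs(tr$z_m[nrow(tr)]), 1e-3)
    expect_lt(abs(tr$z_f[nrow(tr)]), 1e-3)
  }
})

test_that("equal-rate limit: rho = 0, S_m = S_f gives identical XY and ZW recovery", {
  grid <- seq(0, 0.02, length.out = 80)
  xy <- solve_expected(headline_params("XY", S_m = 0.5, S_f = 0.5, rho = 0),
                       tau_grid = grid)
  zw <- solve_expected(headline_params("ZW", S_m = 0.5, S_f = 0.5, rho = 0),
                       tau_grid = grid)
  expect_equal(xy$z_m, zw$z_f, tolerance = 1e-12)
})

test_that("gradual Y/W decay starts at z0/2 and declines monotonically", {
  y <- degradation_profile(c(0, 10, 100, 1e4), alpha = 2e-4, z0 = 1)
  expect_equal(y[1], 0.5)
  expect_true(all(diff(y) < 0))
  # larger alpha decays faster at fixed t
  expect_lt(degradation_profile(500, 4e-4, 1), degradation_profile(500, 2e-4, 1))
  expect_lt(degradation_profile(1e6, 2e-4, 1), 1e-10)
  expect_error(degradation_profile(1, alpha = 0, z0 = 1))
})

test_that("gradual-degradation trajectories start at the optimum and sink", {
  # alpha fast relative to compensation so the transient deficit is visible
  # (at the default alpha the population tracks the slow decay almost
  # perfectly and the dip is tiny)
  p <- headline_params(degradation = "gradual", alpha = 2e-3)
  tr <- solve_expected(p, method = "numeric")
  expect_equal(c(tr$z_m[1], tr$z_f[1]), c(0, 0))
  expect_lt(min(tr$z_m), -0.05)  # deficit builds as the Y copy decays
})

test_that("stationary variance is symmetric, Ne-monotone and mu-free", {
  p_xy <- dc_params("XY", S_m = 0.9, S_f = 0.2, rho = 0.5, Ne = 800)
  p_zw <- dc_params("ZW", S_m = 0.2, S_f = 0.9, rho = 0.5, Ne = 800)
  expect_equal(as.numeric(stationary_variance(p_xy)),
               as.numeric(stationary_variance(p_zw)), tolerance = 1e-12)
  v <- vapply(c(100, 400, 1600), function(ne)
    as.numeric(stationary_variance(dc_params(S_m = 1, S_f = 0.3, rho = 0.4,
                                             Ne = ne))), numeric(1))
  expect_true(all(diff(v) < 0))
  # closed rho = 0 form: 3 / (4 Ne S_het), independent of sigma2 and mu
  p0 <- dc_params(S_m = 0.5, S_f = 1, rho = 0, Ne = 600, sigma2 = 0.02,
                  mu = 1e-5)
  expect_equal(as.numeric(stationary_variance(p0)), 3 / (4 * 600 * 0.5),
               tolerance = 1e-12)
})

test_that("recovery_time finds the 90% crossing", {
  p <- headline_params(S_m = 1, S_f = 1, rho = 0)
  tr <- solve_expected(p)
  tau90 <- recovery_time(tr, 0.9)
  rate <- 10 * p$sigma2 * p$Ne * p$S_m
  expect_equal(tau90, log(10) / rate, tolerance = 1e-3)
  expect_equal(recovery_time(tr, 0.9, units = "generations"),
               unscale_time(tau90, p$mu), tolerance = 1e-9)
})

test_that("trajectories export as TSV with t, tau, z_m, z_f", {
  tr <- solve_expected(headline_params(), tau_grid = seq(0, 0.01, length.out = 5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_trajectory(tr, path)
  back <- read.delim(path)
  expect_identical(names(back), c("t", "tau", "z_m", "z_f"))
  expect_equal(back$z_m, tr$z_m, tolerance = 1e-12)
})
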