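# Maxwell-Wiechert stress-relaxation fitting and derived quantities.

test_that("mw_stress evaluates the biexponential decay", {
  fit <- mw_fit(sigma0 = 2, weights = c(0.5, 0.5), taus = c(100, 1000), plateau = 0)
  expect_equal(mw_stress(0, fit), 2)
  # direct-evaluation oracle at the half-stress crossing
  expect_equal(mw_stress(180.2, fit) / 2, 0.5, tolerance = 1e-3)

  elastic <- mw_fit(sigma0 = 3, weights = c(0, 0), taus = c(10, 100), plateau = 1)
  expect_equal(mw_stress(c(0, 50, 5000), elastic), rep(3, 3))
  expect_error(mw_stress(-1, fit), class = "invalid_parameter_error")

  # nonincreasing in t for valid fits
  set.seed(11)
  for (i in 1:20) {
    w <- runif(2); p <- runif(1); s <- w[1] + w[2] + p
    f <- mw_fit(1, w / s, sort(10^runif(2, 0, 3)), p / s)
    vals <- mw_stress(seq(0, 5000, length.out = 200), f)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("fit_relaxation recovers single-exponential parameters from noiseless data", {
  g <- gen_relaxation(1.0, 1442.695, sigma0 = 2, t_max = 4000, dt = 1)
  fit <- fit_relaxation(g$curve)
  # the slow tau carries all the weight; compare the weighted dominant arm
  dom <- which.max(fit$weights)
  expect_equal(fit$taus[dom], 1442.695, tolerance = 1e-3)
  expect_lt(fit$plateau, 1e-3)
  expect_equal(fit$sigma0, 2, tolerance = 1e-3)
  expect_lt(fit$residual_rmse, 1e-6)
})

test_that("a constant-stress curve fits as pure plateau with undefined half time", {
  curve <- relaxation_curve(seq(0, 100, by = 1), rep(1.5, 101))
  fit <- fit_relaxation(curve)
  expect_gt(fit$plateau, 0.999)
  expect_true(is.na(fit$tau_half))
})

test_that("half time survives 1% additive noise within 5%", {
  g <- gen_relaxation(c(0.5, 0.5), c(100, 1000), sigma0 = 2, t_max = 4000, dt = 1,
                      noise_sd = 0.02, seed = 42)
  fit <- fit_relaxation(g$curve)
  expect_equal(fit$tau_half, g$truth$params$tau_half, tolerance = 0.05)
})

test_that("half_time matches closed forms and the dense-grid oracle", {
  # single exponential: tau * ln 2 to 1e-6 relative
  f1 <- mw_fit(1, c(1, 0), c(57.3, 1000), 0)
  expect_equal(half_time(f1), 57.3 * log(2), tolerance = 1e-6)
  # plateau >= 0.5: undefined, reported not thrown
  expect_true(is.na(half_time(mw_fit(1, c(0.2, 0.2), c(10, 100), 0.6))))
  # biexponential vs 0.01 s dense-grid root
  f2 <- mw_fit(1, c(0.5, 0.5), c(100, 1000), 0)
  expect_equal(half_time(f2), grid_half_time(c(0.5, 0.5), c(100, 1000)),
               tolerance = 0.011, expected.label = "grid oracle")
  # random parameter draws stay within one grid step of the oracle
  set.seed(7)
  for (i in 1:25) {
    a <- runif(2, 0, 0.5); a <- a / sum(a) * runif(1, 0.6, 1)
    taus <- 10^runif(2, 0.5, 2)
    expect_lt(abs(half_time(mw_fit(1, a, taus, 1 - sum(a))) -
                  grid_half_time(a, taus)), 0.011)
  }
})

test_that("half time scales exactly with the time constants", {
  set.seed(3)
  for (i in 1:10) {
    a <- runif(2); a <- a / sum(a)
    taus <- 10^runif(2, 0, 2.5)
    k <- runif(1, 0.2, 5)
    h1 <- half_time(mw_fit(1, a, taus, 0))
    h2 <- half_time(mw_fit(1, a, k * taus, 0))
    expect_equal(h2, k * h1, tolerance = 1e-6)
  }
})

test_that("initial_modulus is the least-squares slope on the strain window", {
  eps <- seq(0, 0.15, by = 0.005)
  expect_equal(initial_modulus(eps, 2.0 * eps), 2.0)
  expect_equal(initial_modulus(eps, 20.0 * eps), 20.0)
  # quadratic stress: compare to the closed-form LS slope on the window
  sel <- eps >= 0.05 & eps <= 0.10
  x <- eps[sel]; y <- (2 * eps - 3 * eps^2)[sel]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(initial_modulus(eps, 2 * eps - 3 * eps^2), slope)
  expect_error(initial_modulus(eps, 2 * eps, window = c(0.2, 0.3)), class = "data_error")
})

test_that("normalize_sweep anchors G' to 1 at 1 rad/s", {
  sw <- data.frame(omega_rad_s = 10^seq(-1, 1, by = 0.25),
                   g_storage = 2 + 10^seq(-1, 1, by = 0.25),
                   g_loss = 0.3 * (2 + 10^seq(-1, 1, by = 0.25)))
  ns <- normalize_sweep(sw)
  expect_equal(ns$g_storage[sw$omega_rad_s == 1], 1.0)
  # purely elastic: zero loss modulus stays zero
  sw$g_loss <- 0
  expect_true(all(normalize_sweep(sw)$g_loss == 0))
  # no sample at 1 rad/s: normalizer is the log-linear interpolant
  sw2 <- data.frame(omega_rad_s = c(0.5, 2), g_storage = c(4, 8), g_loss = c(1, 2))
  gref <- 4 + (8 - 4) * (log(1) - log(0.5)) / (log(2) - log(0.5))
  expect_equal(attr(normalize_sweep(sw2), "g_ref"), gref)
  expect_error(normalize_sweep(data.frame(omega_rad_s = c(2, 4),
                                          g_storage = c(1, 2), g_loss = c(0, 0))),
               class = "data_error")
})

test_that("relaxation_curve validates its inputs", {
  expect_error(relaxation_curve(0:5, rep(1, 6)), class = "data_error")    # too short
  expect_error(relaxation_curve(seq(0, 10, 1), c(rep(1, 10), NA)), class = "data_error")
  expect_error(relaxation_curve(seq(1, 11, 1), rep(1, 11)), class = "data_error")  # not from 0
})
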