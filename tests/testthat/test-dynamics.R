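# Drift/rotation correction, time-averaged MSD, and the power-law fit.

test_that("estimate_rotation solves the orthogonal Procrustes problem", {
  L <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1, 0.5, 0.5, -0.3, 0.7), ncol = 2)
  expect_equal(estimate_rotation(L, L), diag(2), tolerance = 1e-12)

  R <- rot2(pi / 6)
  moved <- t(R %*% t(sweep(L, 2, colMeans(L)))) + 3
  expect_equal(estimate_rotation(moved, L), R, tolerance = 1e-9)

  # noisy correspondences: matches the brute-force angle grid at 0.01 degrees
  set.seed(21)
  noisy <- t(rot2(0.4) %*% t(L)) + matrix(rnorm(nrow(L) * 2, 0, 0.05), ncol = 2)
  Rhat <- estimate_rotation(noisy, L)
  expect_equal(atan2(Rhat[2, 1], Rhat[1, 1]), grid_rotation_angle(noisy, L),
               tolerance = 0.01 * pi / 180 * 1.5)

  expect_error(estimate_rotation(matrix(0, 3, 3),
                                 matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = FALSE)),
               class = "invalid_geometry_error")
})

test_that("mean_rotation is the chordal mean (circular mean in 2D)", {
  expect_equal(mean_rotation(list(diag(2), diag(2))), diag(2))
  pm <- mean_rotation(list(rot2(10 * pi / 180), rot2(-10 * pi / 180)))
  expect_equal(pm, diag(2), tolerance = 1e-12)
  m <- mean_rotation(lapply(c(0, 10, 20) * pi / 180, rot2))
  expect_equal(atan2(m[2, 1], m[1, 1]), 10 * pi / 180, tolerance = 1e-12)
  expect_error(mean_rotation(list(rot2(0), rot2(pi))), class = "degenerate_input_error")
})

test_that("correct_drift subtracts the center track frame-wise", {
  tk <- gen_tracks(1, seed = 6)$tracks[[1]]
  same <- correct_drift(tk, tk)
  expect_true(all(same$position == 0))

  off <- trajectory(2, tk$time, tk$position + 1.5)
  corr <- correct_drift(off, tk)
  expect_equal(corr$position, matrix(1.5, 20, 2))
  expect_true(all(time_avg_msd(corr)$msd < 1e-24))

  # imposed drift is removed exactly
  drift <- outer(0:19, c(0.2, -0.4))
  drifted <- trajectory(3, tk$time, tk$position + drift)
  expect_equal(correct_drift(drifted, drift)$position, tk$position, tolerance = 1e-12)
})

test_that("correct_rotation inverts rigid rotation per frame; mean mode leaves residue", {
  static <- trajectory(1, (0:19) * 120, cbind(rep(3, 20), rep(0, 20)))
  mo <- gen_nucleus_motion(20, c(0, 0), pi / 30, seed = 2)
  obs <- compose_observed_tracks(list(static), mo)[[1]]

  # before correction: off-center static point obeys msd = 2 rho^2 (1 - cos w tau)
  msd_raw <- time_avg_msd(obs)
  w <- pi / 30 / 120
  expect_equal(msd_raw$msd, 2 * 9 * (1 - cos(w * msd_raw$lag)), tolerance = 1e-9)

  per_frame <- correct_rotation(obs, mo$rotations)
  expect_lt(max(time_avg_msd(per_frame)$msd), 1e-18)
  expect_equal(attr(per_frame, "rotation_mode"), "per-frame")

  mean_mode <- correct_rotation(obs, mean_rotation(mo$rotations))
  expect_gt(max(time_avg_msd(mean_mode)$msd), 0.01)
  expect_equal(attr(mean_mode, "rotation_mode"), "mean")

  expect_error(correct_rotation(obs, matrix(c(1, 0, 0, 2), 2, 2)),
               class = "invalid_geometry_error")
})

test_that("the full correction pipeline inverts the forward model", {
  tk <- gen_tracks(5, seed = 5)$tracks
  mo <- gen_nucleus_motion(20, drift_per_frame = c(0.3, -0.2),
                           rotation_per_frame = pi / 40, seed = 7)
  obs <- compose_observed_tracks(tk, mo)
  for (i in seq_along(tk)) {
    rec <- correct_rotation(correct_drift(obs[[i]], mo$center_track), mo$rotations)
    expect_lt(max(abs(rec$position - tk[[i]]$position)), 1e-9)
  }
})

test_that("time_avg_msd matches closed forms and the brute-force oracle", {
  # static particle
  static <- trajectory(1, 0:9, matrix(5, 10, 2))
  expect_true(all(time_avg_msd(static)$msd == 0))

  # constant velocity: msd(tau) = v^2 tau^2 exactly
  v <- c(0.3, -0.1)
  ball <- trajectory(1, (0:19) * 2, outer(0:19 * 2, v))
  msd <- time_avg_msd(ball)
  expect_equal(msd$msd, sum(v^2) * msd$lag^2, tolerance = 1e-12)
  expect_equal(msd$n_pairs, 19:1)

  # exact agreement with the O(N^2) double loop
  set.seed(33)
  for (i in 1:20) {
    pos <- matrix(cumsum(rnorm(40)), 20, 2)
    tr <- trajectory(i, (0:19) * 120, pos)
    expect_identical(time_avg_msd(tr)$msd, brute_force_msd(pos, tr$time))
  }

  # literal-sum convention
  expect_equal(time_avg_msd(ball, average = FALSE)$msd, msd$msd * msd$n_pairs)
  expect_error(time_avg_msd(trajectory(1, 0:1, matrix(0, 2, 2))), class = "data_error")
})

test_that("fit_powerlaw is exact on exact power laws and applies the R^2 gate", {
  lag <- (1:19) * 120
  msd <- structure(data.frame(lag = lag, msd = 0.04 * lag^0.8, n_pairs = 19:1),
                   class = c("msd_curve", "data.frame"))
  fit <- fit_powerlaw(msd)
  expect_equal(fit$alpha, 0.8, tolerance = 1e-12)
  expect_equal(fit$D, 0.04, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$accepted)
  expect_equal(fit$n_lags_fit, 9L)

  # constructed rejection: alternating msd gives a log-log fit below the gate
  bad <- msd
  bad$msd <- 0.04 * rep(c(10, 0.1), length.out = 19)
  bfit <- fit_powerlaw(bad)
  expect_lte(bfit$r_squared, 0.8)
  expect_false(bfit$accepted)
  expect_true(is.na(bfit$T))
  expect_true(is.na(diffusion_time(bfit)))

  zero <- msd; zero$msd[2] <- 0
  expect_error(fit_powerlaw(zero), class = "data_error")
})

test_that("diffusion_time implements T = (1/D)^(1/alpha)", {
  mk <- function(alpha, D) structure(list(alpha = alpha, D = D, r_squared = 0.99,
                                          accepted = TRUE, T = (1 / D)^(1 / alpha)),
                                     class = "powerlaw_fit")
  expect_equal(diffusion_time(mk(0.37, 1)), 1)
  expect_equal(diffusion_time(mk(1.7, 1)), 1)
  expect_equal(diffusion_time(mk(1, 0.04)), 25)
  expect_equal(diffusion_time(mk(0.8, 0.04)), 25^1.25, tolerance = 1e-12)
  expect_equal(diffusion_time(mk(0.8, 0.04)), 55.9, tolerance = 1e-3)
})

test_that("ensemble_summary aggregates accepted fits and counts rejections", {
  one <- fit_powerlaw(structure(data.frame(lag = (1:19) * 120,
                                           msd = 0.04 * ((1:19) * 120)^0.8,
                                           n_pairs = 19:1),
                                class = c("msd_curve", "data.frame")))
  s <- ensemble_summary(list(one, one, one))
  expect_equal(s$alpha_mean, 0.8, tolerance = 1e-12)
  expect_equal(s$n_accepted, 3)
  expect_equal(s$n_rejected, 0)

  rej <- one; rej$accepted <- FALSE; rej$alpha <- 99; rej$T <- NA_real_
  s2 <- ensemble_summary(list(one, rej, one, rej))
  expect_equal(s2$n_accepted, 2)
  expect_equal(s2$n_rejected, 2)
  expect_equal(s2$alpha_mean, 0.8, tolerance = 1e-12)  # rejected fits excluded

  # two generated conditions keep their ground-truth ordering
  slow <- gen_tracks(60, alpha = 0.5, D = 0.02, seed = 51)$tracks
  fast <- gen_tracks(60, alpha = 1.5, D = 0.02, seed = 52)$tracks
  fits <- lapply(c(slow, fast), function(tr) fit_powerlaw(time_avg_msd(tr)))
  cond <- rep(c("slow", "fast"), each = 60)
  s3 <- ensemble_summary(fits, cond)
  expect_lt(s3$alpha_median[s3$condition == "slow"],
            s3$alpha_median[s3$condition == "fast"])
})
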