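# Stress-relaxation analysis: two-element Maxwell-Wiechert biexponential fits,
# relaxation half time, initial modulus from compression ramps, and frequency
# sweep normalization.

#' Construct a stress-relaxation curve
#'
#' A stress-time record acquired while a gel is held at constant compressive
#' strain. Time starts at 0 (the moment the ramp stops) and must be strictly
#' increasing.
#'
#' @param time Time in seconds, strictly increasing, starting at 0.
#' @param stress Stress in kPa, finite, same length as `time`.
#' @param strain The constant strain held during relaxation (dimensionless).
#' @return An object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(time, stress, strain = 0.15) {
  if (length(time) != length(stress)) stop_shape("time and stress must have equal length")
  if (length(time) < 10L) stop_data("a relaxation curve needs at least 10 samples")
  if (!all(is.finite(time)) || !all(is.finite(stress))) stop_data("non-finite values in relaxation curve")
  if (time[1] != 0 || any(diff(time) <= 0)) stop_data("time must be strictly increasing and start at 0")
  structure(list(time = time, stress = stress, strain = strain),
            class = "relaxation_curve")
}

#' Construct a Maxwell-Wiechert fit object
#'
#' Parameterization of the biexponential stress decay
#' \eqn{\sigma(t) = \sigma_0 [p + a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}]}
#' for a two-element Maxwell-Wiechert model (a spring of weight `plateau`
#' in parallel with two Maxwell arms). Weights and plateau lie in \[0, 1\]
#' and sum to 1; the relaxation half time `tau_half` is defined only when
#' the plateau is below 0.5 (otherwise the stress never halves).
#'
#' @param sigma0 Initial stress sigma(0) in kPa.
#' @param weights Two Maxwell arm weights `c(a1, a2)`.
#' @param taus Two relaxation time constants in seconds, `tau1 <= tau2`.
#' @param plateau Non-relaxing (elastic) weight.
#' @param residual_rmse Root-mean-square fit residual in kPa.
#' @return An object of class `mw_fit` with the half time precomputed.
#' @export
mw_fit <- function(sigma0, weights, taus, plateau, residual_rmse = NA_real_) {
  if (!is_scalar_num(sigma0) || sigma0 < 0) stop_invalid_parameter("sigma0 must be a nonnegative scalar")
  if (length(weights) != 2L || length(taus) != 2L) stop_invalid_parameter("need exactly two Maxwell arms")
  if (any(taus <= 0)) stop_invalid_parameter("time constants must be positive")
  tot <- sum(weights) + plateau
  if (any(weights < -1e-8) || plateau < -1e-8 || abs(tot - 1) > 1e-6) {
    stop_invalid_parameter("weights and plateau must be in [0,1] and sum to 1")
  }
  ord <- order(taus)
  fit <- structure(list(sigma0 = sigma0,
                        weights = pmax(weights[ord], 0),
                        taus = taus[ord],
                        plateau = max(plateau, 0),
                        tau_half = NA_real_,
                        residual_rmse = residual_rmse),
                   class = "mw_fit")
  fit$tau_half <- half_time(fit)
  fit
}

#' Evaluate the Maxwell-Wiechert stress decay
#'
#' @param t Times in seconds, nonnegative.
#' @param fit An `mw_fit`.
#' @return Stress in kPa at each `t`.
#' @export
mw_stress <- function(t, fit) {
  stopifnot(inherits(fit, "mw_fit"))
  if (any(t < 0)) stop_invalid_parameter("negative time in mw_stress")
  fit$sigma0 * (fit$plateau +
                fit$weights[1] * exp(-t / fit$taus[1]) +
                fit$weights[2] * exp(-t / fit$taus[2]))
}

# tau starting grid used for multi-start fitting: documented, deterministic.
mw_start_grid <- function(t_max) {
  cand <- c(t_max / 100, t_max / 10, t_max)
  grid <- expand.grid(tau1 = cand, tau2 = cand)
  grid[grid$tau1 <= grid$tau2, , drop = FALSE]
}

#' Fit a relaxation curve with the two-element Maxwell-Wiechert model
#'
#' Bounded Levenberg-Marquardt least squares of
#' \eqn{\sigma(t) = p_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}} with all
#' amplitudes constrained nonnegative, so the fitted weights and plateau are
#' automatically a partition of 1. Initialization is a deterministic
#' multi-start over pairs of time constants at `t_max/100`, `t_max/10` and
#' `t_max`; the start with the lowest residual sum of squares wins, ties
#' broken by the smaller `tau1`.
#'
#' @param curve A [relaxation_curve()].
#' @param pin_plateau If `TRUE`, force the equilibrium plateau to 0
#'   (a fully relaxing, purely viscoelastic model).
#' @return An [mw_fit()] carrying `tau_half` and `residual_rmse`.
#' @export
fit_relaxation <- function(curve, pin_plateau = FALSE) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (!all(is.finite(curve$stress))) stop_data("non-finite stress values")
  s0 <- curve$stress[1]
  if (s0 <= 0) stop_data("initial stress must be positive")
  t <- curve$time
  y <- curve$stress
  t_max <- max(t)
  dat <- data.frame(t = t, y = y)

  starts <- mw_start_grid(t_max)
  best <- NULL
  best_ss <- Inf
  tau_lo <- max(min(diff(t)) / 10, 1e-6)
  for (i in seq_len(nrow(starts))) {
    st <- list(p0 = if (pin_plateau) 0 else 0.2 * s0,
               A1 = 0.4 * s0, A2 = 0.4 * s0,
               tau1 = starts$tau1[i], tau2 = starts$tau2[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ p0 + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
        data = dat, start = st,
        lower = c(p0 = 0, A1 = 0, A2 = 0, tau1 = tau_lo, tau2 = tau_lo),
        upper = c(p0 = if (pin_plateau) 1e-12 else Inf,
                  A1 = Inf, A2 = Inf, tau1 = Inf, tau2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    tol <- 1e-12 * max(abs(ss), abs(if (is.finite(best_ss)) best_ss else 0), 1)
    better <- is.null(best) || ss < best_ss - tol
    tied <- !is.null(best) && abs(ss - best_ss) <= tol &&
      min(stats::coef(fit)[c("tau1", "tau2")]) < min(stats::coef(best)[c("tau1", "tau2")])
    if (better || tied) {
      best <- fit
      best_ss <- ss
    }
  }
  if (is.null(best)) {
    # non-decaying (near-constant) records leave the exponential amplitudes
    # unidentifiable and LM cannot start; fall back to the pure-plateau model
    if (pin_plateau) stop_convergence("Maxwell-Wiechert fit failed for all starts")
    p0 <- mean(y)
    if (p0 <= 0) stop_convergence("Maxwell-Wiechert fit failed for all starts")
    return(mw_fit(sigma0 = p0, weights = c(0, 0),
                  taus = c(t_max / 10, t_max), plateau = 1,
                  residual_rmse = sqrt(mean((y - p0)^2))))
  }

  cf <- stats::coef(best)
  sigma0 <- cf[["p0"]] + cf[["A1"]] + cf[["A2"]]
  if (sigma0 <= 0) stop_convergence("degenerate fit: zero total amplitude")
  out <- mw_fit(sigma0 = sigma0,
                weights = c(cf[["A1"]], cf[["A2"]]) / sigma0,
                taus = c(cf[["tau1"]], cf[["tau2"]]),
                plateau = cf[["p0"]] / sigma0,
                residual_rmse = sqrt(mean(stats::resid(best)^2)))
  out
}

#' Relaxation / recovery half time
#'
#' For a Maxwell-Wiechert fit, the time at which the modeled stress falls to
#' half its initial value, found by bracketed root finding on the fitted
#' model (not on the raw data). Undefined — returned as `NA` — when the
#' elastic plateau holds 50% or more of the initial stress, since the stress
#' then never halves.
#'
#' @param fit A fitted model object.
#' @param ... Passed to methods.
#' @return Half time in seconds, or `NA_real_` when undefined.
#' @export
half_time <- function(fit, ...) UseMethod("half_time")

#' @rdname half_time
#' @export
half_time.mw_fit <- function(fit, ...) {
  if (fit$plateau >= 0.5) return(NA_real_)
  f <- function(t) {
    fit$plateau +
      fit$weights[1] * exp(-t / fit$taus[1]) +
      fit$weights[2] * exp(-t / fit$taus[2]) - 0.5
  }
  upper <- 100 * max(fit$taus)
  # f(0) = 0.5 > 0 and f(upper) < 0 whenever plateau < 0.5
  stats::uniroot(f, c(0, upper), tol = max(fit$taus) * 1e-10)$root
}

#' Initial modulus from a compression stress-strain ramp
#'
#' Ordinary least-squares slope of stress against strain restricted to a
#' strain window (default 5-10% strain, the quasi-linear regime of a 15%
#' compression ramp).
#'
#' @param strain Dimensionless strain, nondecreasing.
#' @param stress Stress in kPa.
#' @param window Strain interval used for the slope, default `c(0.05, 0.10)`.
#' @return Modulus E in kPa.
#' @export
initial_modulus <- function(strain, stress, window = c(0.05, 0.10)) {
  if (length(strain) != length(stress)) stop_shape("strain and stress must have equal length")
  if (any(diff(strain) < 0)) stop_data("strain must be nondecreasing")
  sel <- strain >= window[1] & strain <= window[2]
  if (sum(sel) < 3L) stop_data("fewer than 3 samples inside the strain window")
  unname(stats::coef(stats::lm(stress[sel] ~ strain[sel]))[2])
}

#' Normalize an oscillatory frequency sweep
#'
#' Divides the storage and loss moduli by the storage modulus at
#' 1 rad/s, interpolated log-linearly in frequency when no sample sits
#' exactly at 1 rad/s. The normalized G' at 1 rad/s is 1 by construction.
#'
#' @param sweep A data frame with columns `omega_rad_s`, `g_storage`, `g_loss`.
#' @return The sweep with moduli replaced by their dimensionless normalized
#'   values; the normalizer is attached as attribute `"g_ref"`.
#' @export
normalize_sweep <- function(sweep) {
  need <- c("omega_rad_s", "g_storage", "g_loss")
  if (!all(need %in% names(sweep))) stop_schema("sweep needs columns omega_rad_s, g_storage, g_loss")
  if (any(sweep$omega_rad_s <= 0)) stop_data("omega must be positive")
  if (min(sweep$omega_rad_s) > 1 || max(sweep$omega_rad_s) < 1) {
    stop_data("sweep does not cover 1 rad/s")
  }
  g_ref <- stats::approx(log(sweep$omega_rad_s), sweep$g_storage, xout = 0)$y
  if (!is.finite(g_ref) || g_ref <= 0) stop_data("nonpositive storage modulus at 1 rad/s")
  out <- sweep
  out$g_storage <- sweep$g_storage / g_ref
  out$g_loss <- sweep$g_loss / g_ref
  attr(out, "g_ref") <- g_ref
  out
}

#' @export
print.mw_fit <- function(x, ...) {
  cat("Two-element Maxwell-Wiechert fit\n")
  cat(sprintf("  sigma0   : %.4g kPa\n", x$sigma0))
  cat(sprintf("  weights  : a1 = %.4g, a2 = %.4g, plateau = %.4g\n",
              x$weights[1], x$weights[2], x$plateau))
  cat(sprintf("  taus     : %.4g s, %.4g s\n", x$taus[1], x$taus[2]))
  cat(sprintf("  tau_half : %s\n",
              if (is.na(x$tau_half)) "undefined (plateau >= 0.5)" else sprintf("%.4g s", x$tau_half)))
  cat(sprintf("  RMSE     : %.3g kPa\n", x$residual_rmse))
  invisible(x)
}
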