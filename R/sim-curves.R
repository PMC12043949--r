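# Synthetic curve generators: stress-relaxation records and FRAP traces with
# known ground truth.

#' Ground truth attached to synthetic data
#'
#' Every generator returns, alongside the data, the parameters that produced
#' it (and derived analytic quantities such as half times), so recovery by
#' the analysis modules can be tested against known values.
#'
#' @param kind A short label for the data type.
#' @param params Named list of finite parameter values.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params) {
  stopifnot(is.character(kind), is.list(params))
  structure(list(kind = kind, params = params), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth [", x$kind, "]\n", sep = "")
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    cat(sprintf("  %-18s %s\n", nm, paste(signif(unlist(v), 6), collapse = ", ")))
  }
  invisible(x)
}

# Analytic half time of plateau + sum(a_i exp(-t/tau_i)); NA when the decay
# never reaches half of the initial value.
analytic_half_time <- function(amplitudes, taus) {
  plateau <- 1 - sum(amplitudes)
  if (plateau >= 0.5) return(NA_real_)
  f <- function(t) plateau + sum(amplitudes * exp(-t / taus)) - 0.5
  stats::uniroot(Vectorize(f), c(0, 100 * max(taus)), tol = max(taus) * 1e-12)$root
}

#' Generate a synthetic stress-relaxation curve
#'
#' Multi-exponential stress decay under constant strain,
#' \eqn{\sigma(t) = \sigma_0 [p + \sum_i a_i e^{-t/\tau_i}]} with
#' \eqn{p = 1 - \sum_i a_i} a non-relaxing plateau, plus additive Gaussian
#' noise. Emulates compression-test records from alginate hydrogels.
#'
#' @param amplitudes Nonnegative relaxing weights summing to at most 1.
#' @param taus Time constants in seconds, one per amplitude, all positive.
#' @param sigma0 Initial stress in kPa.
#' @param t_max Record length in seconds.
#' @param dt Sampling interval in seconds.
#' @param noise_sd Additive Gaussian noise SD in kPa.
#' @param seed Integer seed; all randomness is scoped to it.
#' @return A list with elements `curve` (a [relaxation_curve()]) and `truth`
#'   (a [ground_truth()] carrying the analytic half time when it exists).
#' @export
gen_relaxation <- function(amplitudes, taus, sigma0 = 2, t_max = 4000, dt = 1,
                           noise_sd = 0, seed = 1) {
  if (length(amplitudes) != length(taus)) stop_invalid_parameter("amplitudes and taus must have equal length")
  if (any(amplitudes < 0) || sum(amplitudes) > 1 + 1e-12) {
    stop_invalid_parameter("amplitudes must be nonnegative and sum to at most 1")
  }
  if (any(taus <= 0)) stop_invalid_parameter("taus must be positive")
  if (!is_scalar_num(dt) || dt <= 0) stop_invalid_parameter("dt must be positive")
  if (!is_scalar_num(t_max) || t_max <= 0) stop_invalid_parameter("t_max must be positive")

  plateau <- 1 - sum(amplitudes)
  t <- seq(0, t_max, by = dt)
  decay <- rep(plateau, length(t))
  for (i in seq_along(amplitudes)) {
    decay <- decay + amplitudes[i] * exp(-t / taus[i])
  }
  stress <- sigma0 * decay
  if (noise_sd > 0) {
    stress <- stress + with_nm_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  truth <- ground_truth("relaxation", list(
    sigma0 = sigma0, amplitudes = amplitudes, taus = taus, plateau = plateau,
    tau_half = analytic_half_time(amplitudes, taus), noise_sd = noise_sd))
  list(curve = relaxation_curve(t, stress), truth = truth)
}

#' Generate a synthetic FRAP trace
#'
#' Prescan frames at the pre-bleach intensity followed by a
#' single-exponential recovery
#' \eqn{I(t) = I_p - (I_p - I_b) e^{-t/\tau_r}} from the bleach floor
#' `I_bleach` to the plateau `I_plateau`, with additive Gaussian noise.
#' Default acquisition timing: 7 prescan frames at 740 ms, post-bleach
#' frames at 1 s intervals.
#'
#' @param I_pre Pre-bleach intensity (a.u.).
#' @param I_bleach Intensity at the first post-bleach frame.
#' @param I_plateau Recovery plateau; `I_bleach <= I_plateau <= I_pre`
#'   (recovery may be partial).
#' @param tau_r Recovery time constant in seconds.
#' @param protocol A [frap_protocol()].
#' @param noise_sd Additive noise SD (a.u.).
#' @param seed Integer seed.
#' @return A list with elements `trace` (a [frap_trace()]) and `truth`
#'   (carrying `t_half = tau_r * log(2)`).
#' @export
gen_frap_trace <- function(I_pre = 1, I_bleach = 0.3, I_plateau = 0.9,
                           tau_r = 10, protocol = frap_protocol(),
                           noise_sd = 0, seed = 1) {
  if (I_plateau < I_bleach) stop_invalid_parameter("I_plateau must not be below I_bleach")
  if (I_pre < I_plateau) stop_invalid_parameter("I_pre must be at least I_plateau")
  if (!is_scalar_num(tau_r) || tau_r <= 0) stop_invalid_parameter("tau_r must be positive")
  stopifnot(inherits(protocol, "frap_protocol"))

  t_post <- (seq_len(protocol$n_post) - 1L) * protocol$post_interval
  clean_pre <- rep(I_pre, protocol$n_prescan)
  clean_post <- I_plateau - (I_plateau - I_bleach) * exp(-t_post / tau_r)
  if (noise_sd > 0) {
    noise <- with_nm_seed(seed, stats::rnorm(protocol$n_prescan + protocol$n_post, 0, noise_sd))
    clean_pre <- clean_pre + noise[seq_len(protocol$n_prescan)]
    clean_post <- clean_post + noise[-seq_len(protocol$n_prescan)]
  }
  truth <- ground_truth("frap", list(
    I_pre = I_pre, I_bleach = I_bleach, I_plateau = I_plateau,
    tau_r = tau_r, t_half = tau_r * log(2), noise_sd = noise_sd))
  list(trace = frap_trace(t_post, pmax(clean_post, 0), pmax(clean_pre, 0), protocol),
       truth = truth)
}
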