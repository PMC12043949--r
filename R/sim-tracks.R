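# Synthetic particle trajectories: fractional Brownian paths with a known
# anomalous-diffusion law, rigid nucleus motion (drift + rotation), and the
# forward model compositing the two into "observed" tracks.

# Fractional Gaussian noise with unit step variance, exact covariance.
# Primary route: circulant embedding (Davies-Harte); if the embedding is not
# nonnegative definite, falls back to Cholesky of the Toeplitz covariance.
# Must be called inside a seed scope.
fgn_increments <- function(n, H) {
  if (n == 0L) return(numeric(0))
  if (abs(H - 1) < 1e-12) {
    # degenerate ballistic limit: perfectly correlated increments
    return(rep(stats::rnorm(1), n))
  }
  k <- 0:n
  r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  circ <- c(r, rev(r[2:n]))
  lambda <- Re(stats::fft(circ))
  if (all(lambda > -1e-8 * max(lambda))) {
    lambda <- pmax(lambda, 0)
    xi <- stats::rnorm(m) + 1i * stats::rnorm(m)
    z <- stats::fft(sqrt(lambda) * xi) / sqrt(m)
    Re(z)[seq_len(n)]
  } else {
    S <- stats::toeplitz(r[seq_len(n)])
    L <- chol(S + diag(1e-12, n))
    as.numeric(crossprod(L, stats::rnorm(n)))
  }
}

#' Generate fractional-Brownian particle tracks
#'
#' Tracks whose coordinates are independent fractional Brownian paths with
#' Hurst exponent `alpha/2`, scaled so the expected dimension-summed MSD
#' obeys \eqn{E[MSD(\tau)] = D \tau^\alpha}. `D` is the full (dim-summed)
#' prefactor in um^2 s^-alpha; no 2d/4d/6d factor is divided out. The
#' defaults (20 frames at 120-s intervals) mirror live-imaging of nucleolar
#' particles over 40 minutes.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Frames per track (default 20).
#' @param dt Frame interval in seconds (default 120).
#' @param alpha Diffusion exponent in (0, 2]; 1 is Brownian, 2 ballistic.
#' @param D MSD prefactor in um^2 s^-alpha.
#' @param dim 2 or 3 spatial dimensions (default 2).
#' @param seed Integer seed.
#' @return A list with `tracks` (list of [trajectory()]) and `truth`.
#' @export
gen_tracks <- function(n_tracks, n_steps = 20L, dt = 120, alpha = 1, D = 0.01,
                       dim = 2L, seed = 1) {
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha > 2) {
    stop_invalid_parameter("alpha must be in (0, 2]")
  }
  if (!is_scalar_num(D) || D <= 0) stop_invalid_parameter("D must be positive")
  if (!dim %in% c(2L, 3L)) stop_invalid_parameter("dim must be 2 or 3")
  if (n_steps < 2L) stop_invalid_parameter("need at least 2 frames per track")

  H <- alpha / 2
  step_sd <- sqrt((D / dim) * dt^alpha)
  time <- (seq_len(n_steps) - 1L) * dt
  tracks <- with_nm_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      pos <- vapply(seq_len(dim), function(j) {
        c(0, cumsum(fgn_increments(n_steps - 1L, H) * step_sd))
      }, numeric(n_steps))
      trajectory(id = i, time = time, position = pos)
    })
  })
  truth <- ground_truth("tracks", list(alpha = alpha, D = D, dim = dim,
                                       dt = dt, n_steps = n_steps))
  list(tracks = tracks, truth = truth)
}

rotation_matrix <- function(theta, dim = 2L) {
  R2 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (dim == 2L) R2 else rbind(cbind(R2, c(0, 0)), c(0, 0, 1))
}

#' Generate rigid nucleus motion
#'
#' A nucleus center drifting at a constant per-frame displacement while the
#' nucleus rotates about its (moving) center at a constant per-frame angle
#' (about the z axis in 3D). Landmarks are scattered around the initial
#' center and rigidly carried along; optional Gaussian observation jitter
#' can be added to the landmark coordinates.
#'
#' @param n_frames Number of frames.
#' @param drift_per_frame Per-frame drift vector in um (length 2 or 3 sets
#'   the dimension).
#' @param rotation_per_frame Per-frame rotation angle in radians.
#' @param n_landmarks Number of landmarks; at least 2 (2D) or 3 (3D).
#' @param landmark_radius Scatter radius of the landmarks in um.
#' @param jitter_sd Landmark observation noise SD in um.
#' @param seed Integer seed.
#' @return An object of class `nucleus_motion` with `center_track`
#'   (n_frames x dim matrix), `rotations` (list of cumulative rotation
#'   matrices) and `landmarks` (list of n_landmarks x dim matrices).
#' @export
gen_nucleus_motion <- function(n_frames, drift_per_frame = c(0, 0),
                               rotation_per_frame = 0, n_landmarks = 6L,
                               landmark_radius = 5, jitter_sd = 0, seed = 1) {
  dim <- length(drift_per_frame)
  if (!dim %in% c(2L, 3L)) stop_invalid_parameter("drift_per_frame must have length 2 or 3")
  if (n_landmarks < ifelse(dim == 2L, 2L, 3L)) {
    stop_invalid_geometry("need at least 2 landmarks in 2D, 3 in 3D")
  }
  frames <- seq_len(n_frames) - 1L
  center <- outer(frames, drift_per_frame)
  rotations <- lapply(frames, function(k) rotation_matrix(k * rotation_per_frame, dim))

  lm0 <- with_nm_seed(seed, matrix(stats::runif(n_landmarks * dim, -landmark_radius,
                                                landmark_radius),
                                   n_landmarks, dim))
  if (qr(sweep(lm0, 2, colMeans(lm0)))$rank < dim - 1L) {
    stop_invalid_geometry("degenerate landmark configuration")
  }
  jitter <- if (jitter_sd > 0) {
    with_nm_seed(seed + 1L,
                 lapply(seq_len(n_frames),
                        function(i) matrix(stats::rnorm(n_landmarks * dim, 0, jitter_sd),
                                           n_landmarks, dim)))
  } else NULL
  landmarks <- lapply(seq_len(n_frames), function(i) {
    L <- t(rotations[[i]] %*% t(lm0)) + matrix(center[i, ], n_landmarks, dim, byrow = TRUE)
    if (!is.null(jitter)) L <- L + jitter[[i]]
    L
  })
  structure(list(center_track = center, rotations = rotations,
                 landmarks = landmarks),
            class = "nucleus_motion")
}

#' Composite intrinsic tracks with rigid nucleus motion
#'
#' Forward model for the drift/rotation correction inverse problem: each
#' intrinsic (nucleus-frame) position is rotated by the frame's cumulative
#' rotation about the nucleus center and translated by the center track,
#' \eqn{obs(t) = c(t) + R(t) p(t)}. [correct_drift()] followed by
#' [correct_rotation()] in per-frame mode inverts this exactly.
#'
#' @param tracks List of [trajectory()] in the nucleus frame (center at the
#'   origin).
#' @param motion A [gen_nucleus_motion()] result with matching frame count.
#' @return List of observed trajectories.
#' @export
compose_observed_tracks <- function(tracks, motion) {
  stopifnot(inherits(motion, "nucleus_motion"))
  n_frames <- nrow(motion$center_track)
  lapply(tracks, function(tr) {
    if (nrow(tr$position) != n_frames) stop_shape("track/motion frame-count mismatch")
    obs <- t(vapply(seq_len(n_frames), function(i) {
      motion$center_track[i, ] + as.numeric(motion$rotations[[i]] %*% tr$position[i, ])
    }, numeric(ncol(tr$position))))
    trajectory(tr$id, tr$time, obs, tr$valid)
  })
}
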