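# Intranuclear particle dynamics: drift/rotation correction of trajectories,
# time-averaged MSD, anomalous-diffusion power-law fit, and the time to
# diffuse one square micrometre.

#' Construct a particle trajectory
#'
#' A single-particle track on a uniform time grid. Tracks concatenated from
#' different loci are not representable: the valid flags must form one
#' contiguous segment.
#'
#' @param id Track label.
#' @param time Frame times in seconds (uniform grid).
#' @param position n_frames x dim matrix of coordinates in micrometres
#'   (dim 2 or 3).
#' @param valid Optional per-frame logical flags; must be one contiguous run.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(id, time, position, valid = NULL) {
  position <- unname(as.matrix(position))
  if (length(time) != nrow(position)) stop_shape("time and position must have equal frame counts")
  if (!ncol(position) %in% c(2L, 3L)) stop_shape("position must have 2 or 3 columns")
  if (is.null(valid)) valid <- rep(TRUE, length(time))
  r <- rle(valid)
  if (sum(r$values) > 1L) stop_data("valid frames must form a single contiguous segment")
  structure(list(id = id, time = time, position = position, valid = valid),
            class = "trajectory")
}

traj_dim <- function(traj) ncol(traj$position)

as_position_matrix <- function(x, n_frames, dim) {
  m <- if (inherits(x, "trajectory")) x$position else as.matrix(x)
  if (nrow(m) != n_frames || ncol(m) != dim) stop_shape("frame grid mismatch")
  m
}

#' Estimate a rigid rotation between matched landmark sets (Kabsch)
#'
#' Least-squares proper rotation `R` minimizing
#' \eqn{\sum_i \| (p_i - \bar p) - R (q_i - \bar q) \|^2} between a reference
#' landmark set `landmarks_ref` (q) and the set at time t `landmarks_t` (p),
#' via SVD of the centered cross-covariance with the determinant forced
#' to +1.
#'
#' @param landmarks_t k x dim matrix of landmark positions at time t.
#' @param landmarks_ref Matched k x dim reference positions.
#' @return A dim x dim rotation matrix mapping centered reference
#'   coordinates onto centered time-t coordinates.
#' @export
estimate_rotation <- function(landmarks_t, landmarks_ref) {
  P <- as.matrix(landmarks_t)
  Q <- as.matrix(landmarks_ref)
  if (!identical(dim(P), dim(Q))) stop_shape("landmark sets must match in shape")
  d <- ncol(P)
  if (nrow(P) < ifelse(d == 2L, 2L, 3L)) stop_invalid_geometry("too few landmarks")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  if (qr(Qc)$rank < d - 1L) stop_invalid_geometry("degenerate landmark configuration")
  H <- crossprod(Qc, Pc)
  sv <- svd(H)
  s <- diag(c(rep(1, d - 1L), sign(det(sv$v %*% t(sv$u)))))
  sv$v %*% s %*% t(sv$u)
}

#' Chordal mean of rotation matrices
#'
#' Arithmetic average of the matrices projected back onto the rotation
#' group by orthogonal polar projection (SVD with determinant correction).
#' In 2D this is the circular mean of the rotation angles.
#'
#' @param rotations Nonempty list of proper rotation matrices.
#' @return The mean rotation matrix.
#' @export
mean_rotation <- function(rotations) {
  if (length(rotations) == 0L) stop_data("empty rotation list")
  M <- Reduce(`+`, rotations) / length(rotations)
  sv <- svd(M)
  if (min(sv$d) < 1e-10) stop_degenerate("rotation mean is singular (antipodal spread)")
  s <- diag(c(rep(1, ncol(M) - 1L), sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% s %*% t(sv$v)
}

#' Correct a trajectory for nucleus drift
#'
#' Frame-wise subtraction of the nucleus center-of-mass track from the
#' particle track.
#'
#' @param traj A [trajectory()].
#' @param center_track A matching [trajectory()] or n_frames x dim matrix of
#'   nucleus center positions.
#' @return The drift-corrected trajectory.
#' @export
correct_drift <- function(traj, center_track) {
  stopifnot(inherits(traj, "trajectory"))
  ctr <- as_position_matrix(center_track, nrow(traj$position), traj_dim(traj))
  trajectory(traj$id, traj$time, traj$position - ctr, traj$valid)
}

#' Correct a trajectory for nucleus rotation
#'
#' Applies the inverse rotation about a center,
#' \eqn{p(t) \leftarrow R(t)^{-1} (p(t) - c(t)) + c(t)}. Supply either a
#' per-frame list of rotation matrices (exact inverse of rigid motion) or a
#' single per-trajectory mean rotation applied to all frames (the averaged
#' variant; cheaper but only approximate for time-varying rotation). The
#' center defaults to the origin, appropriate for drift-corrected tracks.
#'
#' @param traj A [trajectory()].
#' @param rotations List of per-frame rotation matrices, or one matrix.
#' @param center Optional n_frames x dim matrix (or trajectory) of rotation
#'   centers; defaults to the origin.
#' @return The rotation-corrected trajectory with attribute
#'   `"rotation_mode"` set to `"per-frame"` or `"mean"`.
#' @export
correct_rotation <- function(traj, rotations, center = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$position)
  d <- traj_dim(traj)
  per_frame <- is.list(rotations)
  rots <- if (per_frame) rotations else rep(list(rotations), n)
  if (length(rots) != n) stop_shape("need one rotation per frame")
  for (R in rots) {
    if (!isTRUE(all.equal(crossprod(R), diag(d), tolerance = 1e-6)) || det(R) < 0) {
      stop_invalid_geometry("rotations must be proper orthonormal matrices")
    }
  }
  ctr <- if (is.null(center)) matrix(0, n, d) else as_position_matrix(center, n, d)
  pos <- t(vapply(seq_len(n), function(i) {
    as.numeric(t(rots[[i]]) %*% (traj$position[i, ] - ctr[i, ])) + ctr[i, ]
  }, numeric(d)))
  out <- trajectory(traj$id, traj$time, pos, traj$valid)
  attr(out, "rotation_mode") <- if (per_frame) "per-frame" else "mean"
  out
}

#' Time-averaged mean squared displacement
#'
#' For each lag \eqn{\tau = k \Delta t}, averages the squared displacement
#' \eqn{|r(t+\tau) - r(t)|^2} over all ordered frame pairs within the valid
#' segment of the track. Set `average = FALSE` for the bare sum over pairs
#' instead of the mean.
#'
#' @param traj A [trajectory()] with at least 3 valid frames.
#' @param max_lag_fraction Largest lag as a fraction of the track length.
#' @param average Average over pairs (default) or report the bare sum.
#' @return An object of class `msd_curve`: a data frame with columns `lag`
#'   (s), `msd` (um^2) and `n_pairs`.
#' @export
time_avg_msd <- function(traj, max_lag_fraction = 1.0, average = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  pos <- traj$position[traj$valid, , drop = FALSE]
  tt <- traj$time[traj$valid]
  n <- nrow(pos)
  if (n < 3L) stop_data("need at least 3 valid frames for an MSD")
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop_data("time grid must be uniform")
  max_k <- max(1L, floor((n - 1L) * max_lag_fraction))
  rows <- lapply(seq_len(max_k), function(k) {
    d2 <- rowSums((pos[(k + 1L):n, , drop = FALSE] - pos[1L:(n - k), , drop = FALSE])^2)
    c(lag = k * dt[1], msd = if (average) mean(d2) else sum(d2), n_pairs = n - k)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("msd_curve", class(out))
  out
}

#' Average MSD curves across an ensemble of tracks
#'
#' Pairs-weighted mean of per-track time-averaged MSD curves on the common
#' lag grid.
#'
#' @param trajs List of [trajectory()].
#' @param ... Passed to [time_avg_msd()].
#' @return An `msd_curve` with `n_pairs` summed over tracks.
#' @export
ensemble_msd <- function(trajs, ...) {
  curves <- lapply(trajs, time_avg_msd, ...)
  lags <- sort(unique(unlist(lapply(curves, function(cv) cv$lag))))
  rows <- lapply(lags, function(l) {
    w <- 0; s <- 0
    for (cv in curves) {
      i <- match(l, cv$lag)
      if (!is.na(i)) { s <- s + cv$msd[i] * cv$n_pairs[i]; w <- w + cv$n_pairs[i] }
    }
    c(lag = l, msd = s / w, n_pairs = w)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Ordinary least squares of \eqn{\log_{10} MSD} on \eqn{\log_{10} \tau}
#' over the first `fit_fraction` of the available lags (rounded down,
#' minimum 3). The slope is the diffusion exponent alpha and
#' \eqn{D = 10^{intercept}} the prefactor. The fit is accepted only when
#' \eqn{R^2 >} `r2_min`; for accepted fits the time to diffuse 1 um^2,
#' \eqn{T = (1/D)^{1/\alpha}}, is reported.
#'
#' @param msd An `msd_curve` from [time_avg_msd()] or [ensemble_msd()].
#' @param fit_fraction Fraction of lags used (default 0.5).
#' @param r2_min Acceptance threshold on R^2 (default 0.8).
#' @return An object of class `powerlaw_fit` with fields `alpha`, `D`,
#'   `r_squared`, `accepted`, `T`, `n_lags_fit`.
#' @export
fit_powerlaw <- function(msd, fit_fraction = 0.5, r2_min = 0.8) {
  n_fit <- max(3L, floor(nrow(msd) * fit_fraction))
  if (nrow(msd) < n_fit || n_fit < 3L) stop_data("need at least 3 lags in the fit window")
  w <- msd[seq_len(n_fit), ]
  if (any(w$msd <= 0)) stop_data("nonpositive MSD in the fit window")
  fit <- stats::lm(log10(msd) ~ log10(lag), data = w)
  cf <- stats::coef(fit)
  # exactly sampled power laws fit perfectly; lm's perfect-fit warning is noise here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  alpha <- unname(cf[2])
  D <- 10^unname(cf[1])
  accepted <- is.finite(r2) && r2 > r2_min
  structure(list(alpha = alpha, D = D, r_squared = r2, accepted = accepted,
                 T = if (accepted && D > 0 && alpha > 0) (1 / D)^(1 / alpha) else NA_real_,
                 n_lags_fit = n_fit),
            class = "powerlaw_fit")
}

#' Time to diffuse one square micrometre
#'
#' \eqn{T = (1/D)^{1/\alpha}}: the lag at which the fitted power-law MSD
#' reaches 1 um^2. `NA` for fits rejected by the R^2 gate.
#'
#' @param fit A `powerlaw_fit`.
#' @return T in seconds, or `NA_real_` for unaccepted fits.
#' @export
diffusion_time <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (!isTRUE(fit$accepted)) return(NA_real_)
  if (fit$D <= 0 || fit$alpha <= 0) stop_invalid_parameter("need D > 0 and alpha > 0")
  (1 / fit$D)^(1 / fit$alpha)
}

#' Summarize an ensemble of power-law fits
#'
#' Mean, median and SD of alpha, D and T over the accepted fits, with
#' rejection counts; optionally split by an experimental condition.
#'
#' @param fits List of `powerlaw_fit`.
#' @param condition Optional factor of the same length as `fits`.
#' @return A data frame, one row per condition.
#' @export
ensemble_summary <- function(fits, condition = NULL) {
  if (length(fits) == 0L) stop_data("no fits to summarize")
  if (is.null(condition)) condition <- rep("all", length(fits))
  df <- data.frame(condition = as.character(condition),
                   alpha = vapply(fits, `[[`, numeric(1), "alpha"),
                   D = vapply(fits, `[[`, numeric(1), "D"),
                   T = vapply(fits, `[[`, numeric(1), "T"),
                   accepted = vapply(fits, `[[`, logical(1), "accepted"))
  do.call(rbind, lapply(split(df, df$condition), function(g) {
    a <- g[g$accepted, , drop = FALSE]
    data.frame(condition = g$condition[1],
               n_accepted = nrow(a), n_rejected = sum(!g$accepted),
               alpha_mean = mean(a$alpha), alpha_median = stats::median(a$alpha),
               alpha_sd = stats::sd(a$alpha),
               D_mean = mean(a$D), D_median = stats::median(a$D),
               D_sd = stats::sd(a$D),
               T_mean = mean(a$T), T_median = stats::median(a$T),
               T_sd = stats::sd(a$T),
               row.names = NULL)
  }))
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Anomalous-diffusion power-law fit (log-log OLS)\n")
  cat(sprintf("  alpha = %.4g   D = %.4g um^2 s^-alpha   R^2 = %.4f\n",
              x$alpha, x$D, x$r_squared))
  if (x$accepted) {
    cat(sprintf("  accepted (R^2 gate); T(1 um^2) = %.4g s\n", x$T))
  } else {
    cat("  rejected by the R^2 gate\n")
  }
  invisible(x)
}
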