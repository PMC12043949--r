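# Independent oracles used across the suite: deliberately naive
# implementations kept separate from the package's vectorized paths.

# O(N^2) time-averaged MSD by explicit double loop over ordered frame pairs.
brute_force_msd <- function(position, time) {
  n <- nrow(position)
  dt <- time[2] - time[1]
  vapply(seq_len(n - 1L), function(k) {
    d2 <- numeric(n - k)
    for (t in 1:(n - k)) {
      d2[t] <- sum((position[t + k, ] - position[t, ])^2)
    }
    mean(d2)
  }, numeric(1))
}

# Dense-grid root of plateau + sum(a_i exp(-t/tau_i)) = 0.5 at 0.01 s steps.
grid_half_time <- function(amplitudes, taus, dt = 0.01) {
  plateau <- 1 - sum(amplitudes)
  t <- seq(0, 100 * max(taus), by = dt)
  f <- rep(plateau, length(t))
  for (i in seq_along(amplitudes)) f <- f + amplitudes[i] * exp(-t / taus[i])
  t[which(f <= 0.5)[1]]
}

# Per-label channel means by explicit per-pixel accumulation.
naive_label_means <- function(labels, channel) {
  sums <- list()
  counts <- list()
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == 0) next
    key <- as.character(l)
    sums[[key]] <- (sums[[key]] %||% 0) + channel[i]
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  ids <- sort(as.integer(names(sums)))
  vapply(as.character(ids), function(k) sums[[k]] / counts[[k]], numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Best rigid rotation angle (2D) by brute-force grid search at 0.01 degrees.
grid_rotation_angle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  angles <- seq(-pi, pi, by = 0.01 * pi / 180)
  rmsd <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sum((Pc - t(R %*% t(Qc)))^2)
  }, numeric(1))
  angles[which.min(rmsd)]
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

disk_image <- function(n, cx, cy, r, value = 1, base = 0) {
  img <- matrix(base, n, n)
  img[(col(img) - cx)^2 + (row(img) - cy)^2 <= r^2] <- value
  img
}
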