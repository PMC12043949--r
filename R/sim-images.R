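# Synthetic microscopy: ellipsoidal nucleus z-stacks and 2D lamin-stained
# nucleus images with a controllable boundary-fold (wrinkle) amplitude.
# Default imaging geometry: 0.1 um xy pixels, 0.3 um z-step.

#' Generate a synthetic nucleus z-stack
#'
#' An ellipsoidal nucleus centered in the stack, filled with either a
#' uniform interior intensity or a clumped (smoothed multiplicative
#' texture) one, over a constant background with optional Gaussian noise.
#' Emulates DAPI/Hoechst confocal z-stacks at 300-nm z-steps.
#'
#' @param semi_axes Ellipsoid semi-axes `c(a, b, c)` in um (x, y, z).
#' @param voxel_xy Lateral pixel size in um (default 0.1).
#' @param z_step Axial step in um (default 0.3).
#' @param interior_intensity Mean interior intensity (a.u.).
#' @param texture `"uniform"` or `"clumped"`.
#' @param clump_contrast Relative contrast of the clumped texture.
#' @param background Background intensity (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param margin Clearance between the ellipsoid and the stack faces, um.
#' @param dims Optional stack dimensions `c(ny, nx, nz)`; computed from the
#'   geometry when `NULL`. An ellipsoid that does not fit inside the given
#'   dimensions is an error.
#' @param seed Integer seed.
#' @return A list with `stack` (a [zstack()]) and `truth` carrying the
#'   analytic volume `4/3 pi a b c`.
#' @export
gen_nucleus_stack <- function(semi_axes = c(5, 5, 3), voxel_xy = 0.1,
                              z_step = 0.3, interior_intensity = 100,
                              texture = c("uniform", "clumped"),
                              clump_contrast = 0.5, background = 10,
                              noise_sd = 0, margin = 1, dims = NULL, seed = 1) {
  texture <- match.arg(texture)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop_invalid_parameter("semi_axes must be three positive lengths")
  }
  if (margin < 0) stop_invalid_geometry("margin must be nonnegative")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  if (is.null(dims)) {
    dims <- c(ceiling(2 * (b + margin) / voxel_xy),
              ceiling(2 * (a + margin) / voxel_xy),
              ceiling(2 * (cc + margin) / z_step))
  }
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  if (2 * a > nx * voxel_xy || 2 * b > ny * voxel_xy || 2 * cc > nz * z_step) {
    stop_invalid_geometry("ellipsoid exceeds stack bounds")
  }
  x <- ((seq_len(nx) - 0.5) - nx / 2) * voxel_xy
  y <- ((seq_len(ny) - 0.5) - ny / 2) * voxel_xy
  z <- ((seq_len(nz) - 0.5) - nz / 2) * z_step

  data <- array(background, dim = c(ny, nx, nz))
  xy2 <- outer((y / b)^2, (x / a)^2, `+`)
  inside_any <- FALSE
  interior <- if (texture == "clumped") {
    with_nm_seed(seed + 1L, {
      lapply(seq_len(nz), function(k) {
        g <- EBImage::gblur(matrix(stats::rnorm(ny * nx), ny, nx), sigma = 3)
        g <- g / stats::sd(g)
        interior_intensity * pmax(1 + clump_contrast * g, 0.1)
      })
    })
  } else NULL
  for (k in seq_len(nz)) {
    inside <- xy2 + (z[k] / cc)^2 <= 1
    if (!any(inside)) next
    inside_any <- TRUE
    sl <- data[, , k]
    sl[inside] <- background +
      if (texture == "uniform") interior_intensity else interior[[k]][inside]
    data[, , k] <- sl
  }
  if (!inside_any) stop_invalid_geometry("ellipsoid does not intersect the voxel grid")
  if (noise_sd > 0) {
    data <- data + with_nm_seed(seed, array(stats::rnorm(length(data), 0, noise_sd), dim(data)))
  }
  data <- pmax(data, 0)
  truth <- ground_truth("nucleus_stack", list(
    semi_axes = semi_axes, volume_um3 = 4 / 3 * pi * a * b * cc,
    interior_intensity = interior_intensity, background = background,
    voxel_xy = voxel_xy, z_step = z_step))
  list(stack = zstack(data, voxel_xy = voxel_xy, z_step = z_step), truth = truth)
}

#' Generate a synthetic lamin-stained nucleus image
#'
#' A disk-shaped nucleus with a bright lamina rim and, inside, a smoothed
#' sinusoidal ridge field standing in for lamina folds. The ridge field has
#' a fixed spatial wavelength (in pixels), so fold coverage per unit area is
#' independent of the nucleus radius, and its contrast scales linearly with
#' `fold_amplitude`.
#'
#' @param radius Nucleus radius in um.
#' @param fold_amplitude Ridge contrast (a.u.); 0 gives a fold-free nucleus.
#' @param n_folds Number of sinusoidal wave components (0 disables folds).
#' @param pixel Pixel size in um (default 0.1).
#' @param wavelength Fold wavelength in pixels (default 8).
#' @param interior Interior base intensity (rim is 1.0, background 0.05).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list with `image` (2D matrix in \[0, ~1\]), `mask` (logical
#'   disk mask) and `truth` recording `fold_amplitude`.
#' @export
gen_lamin_image <- function(radius = 4, fold_amplitude = 0.1, n_folds = 4L,
                            pixel = 0.1, wavelength = 8, interior = 0.4,
                            noise_sd = 0, seed = 1) {
  if (fold_amplitude < 0) stop_invalid_parameter("fold_amplitude must be nonnegative")
  r_px <- radius / pixel
  pad <- ceiling(0.2 * r_px) + 8L
  n <- as.integer(2 * ceiling(r_px + pad))
  cx <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  ys <- matrix(seq_len(n), n, n) - cx
  rr <- sqrt(xs^2 + ys^2)
  mask <- rr <= r_px

  rim_width <- 1.5
  img <- matrix(0.05, n, n)
  img[mask] <- interior
  # lamina rim: a band just inside the nucleus boundary
  img[rr <= r_px & rr >= r_px - 2 * rim_width] <- 1.0

  if (n_folds > 0L && fold_amplitude > 0) {
    field <- matrix(0, n, n)
    angles <- with_nm_seed(seed + 1L, list(
      theta = stats::runif(n_folds, 0, pi),
      phase = stats::runif(n_folds, 0, 2 * pi)))
    for (j in seq_len(n_folds)) {
      u <- xs * cos(angles$theta[j]) + ys * sin(angles$theta[j])
      field <- field + sin(2 * pi * u / wavelength + angles$phase[j])
    }
    field <- field / sqrt(n_folds)
    core <- rr <= r_px - 2 * rim_width  # folds live in the interior, off the rim
    img[core] <- img[core] + fold_amplitude * field[core]
  }
  img <- EBImage::gblur(img, sigma = 1)
  if (noise_sd > 0) {
    img <- img + with_nm_seed(seed, matrix(stats::rnorm(n * n, 0, noise_sd), n, n))
  }
  truth <- ground_truth("lamin_image", list(
    radius_um = radius, fold_amplitude = fold_amplitude, n_folds = n_folds,
    pixel = pixel))
  list(image = pmax(img, 0), mask = mask, truth = truth)
}
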