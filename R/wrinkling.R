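# Nuclear-lamina wrinkling: edge-magnitude score inside the eroded
# nucleoplasm of a lamin-stained nucleus, plus the decorrelation check
# against nuclear area and nucleoplasm intensity variation.

#' Segment the nucleus in a 2D lamin image
#'
#' Gaussian blur, Otsu threshold, largest connected component, holes filled.
#'
#' @param image 2D intensity matrix with one dominant nucleus.
#' @param blur_sigma Gaussian blur sigma in pixels (default 2).
#' @param threshold Threshold method; only `"otsu"` is implemented.
#' @return Logical nucleus mask.
#' @export
nucleus_mask <- function(image, blur_sigma = 2, threshold = "otsu") {
  if (length(dim(image)) != 2L) stop_shape("image must be 2D")
  if (threshold != "otsu") stop_invalid_parameter("only the 'otsu' threshold method is implemented")
  sc <- scale01(image)
  if (all(sc == 0)) stop_segmentation("blank image: no intensity variation")
  blurred <- EBImage::gblur(sc, sigma = blur_sigma)
  comp <- largest_component(blurred > EBImage::otsu(blurred, range = c(0, 1)))
  EBImage::fillHull(comp$mask) > 0
}

#' Erode a nucleus mask to its nucleoplasm
#'
#' Binary erosion with a disk structuring element. The erosion radius must
#' be held constant across compared groups; radius 0 is the identity.
#'
#' @param mask Logical nucleus mask.
#' @param erosion_radius Erosion radius in pixels.
#' @return Logical nucleoplasm mask (strictly inside the nucleus for
#'   positive radii).
#' @export
nucleoplasm_mask <- function(mask, erosion_radius) {
  if (erosion_radius < 0) stop_invalid_parameter("erosion_radius must be nonnegative")
  if (erosion_radius == 0) return(mask)
  brush_size <- 2 * round(erosion_radius) + 1
  er <- EBImage::erode(mask, EBImage::makeBrush(brush_size, shape = "disc")) > 0
  if (!any(er)) stop_degenerate("erosion removed the entire mask")
  er
}

#' Gaussian-derivative edge map
#'
#' Gradient magnitude of the Gaussian-smoothed image at a given scale,
#' computed on an intensity-normalized copy (robust rescale of the 1st-99th
#' percentile range to \[0, 1\]), making the map invariant to global gain
#' and offset.
#'
#' @param image 2D intensity matrix.
#' @param scale Gaussian smoothing scale in pixels (default 2).
#' @param normalize Apply the robust percentile normalization
#'   (default `TRUE`).
#' @return Matrix of gradient magnitudes, same shape as `image`.
#' @export
edge_map <- function(image, scale = 2, normalize = TRUE) {
  if (!is_scalar_num(scale) || scale <= 0) stop_invalid_parameter("scale must be positive")
  img <- image
  if (normalize) {
    q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) {
      img <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
    } else {
      img <- img * 0
    }
  }
  sm <- EBImage::gblur(img, sigma = scale)
  n <- nrow(sm); m <- ncol(sm)
  gy <- sm; gx <- sm
  gy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
  gy[c(1, n), ] <- 0
  gx[, 2:(m - 1)] <- (sm[, 3:m] - sm[, 1:(m - 2)]) / 2
  gx[, c(1, m)] <- 0
  sqrt(gx^2 + gy^2)
}

#' Nuclear wrinkling index
#'
#' Mean Gaussian-derivative edge magnitude inside the eroded nucleoplasm of
#' a lamin-stained nucleus. Higher values indicate a more folded lamina.
#' The erosion radius defaults to 10% of the mask's equivalent radius; for
#' group comparisons pass a fixed `erosion_radius` so the same value is
#' used across all images.
#'
#' @param image 2D lamin intensity matrix.
#' @param blur_sigma Blur used for masking, pixels.
#' @param erosion_radius Nucleoplasm erosion radius in pixels; `NULL` for
#'   the 10%-of-equivalent-radius default.
#' @param edge_scale Edge-detection scale in pixels.
#' @param pixel_um Pixel size in um (for the reported area).
#' @param normalize Percentile intensity normalization before edge
#'   detection (default `TRUE`).
#' @return An object of class `wrinkle_result` with fields `index`,
#'   `nucleus_area` (um^2), `nucleoplasm_intensity_cv` and
#'   `erosion_radius`.
#' @export
wrinkling_index <- function(image, blur_sigma = 2, erosion_radius = NULL,
                            edge_scale = 2, pixel_um = 1, normalize = TRUE) {
  mask <- nucleus_mask(image, blur_sigma = blur_sigma)
  if (is.null(erosion_radius)) {
    erosion_radius <- max(1, round(0.1 * sqrt(sum(mask) / pi)))
  }
  nucleo <- nucleoplasm_mask(mask, erosion_radius)
  edges <- edge_map(image, scale = edge_scale, normalize = normalize)
  inside <- image[nucleo]
  cv <- if (mean(inside) > 0) stats::sd(inside) / mean(inside) else NA_real_
  structure(list(index = mean(edges[nucleo]),
                 nucleus_area = sum(mask) * pixel_um^2,
                 nucleoplasm_intensity_cv = cv,
                 erosion_radius = erosion_radius),
            class = "wrinkle_result")
}

#' Check that the wrinkling index is not confounded
#'
#' Pearson correlation of the wrinkling index against nuclear area and
#' against the nucleoplasm intensity coefficient of variation, with
#' two-sided permutation p-values. On valid data the index should not
#' track either covariate.
#'
#' @param results List of `wrinkle_result` (at least 10).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return Data frame with one row per covariate: `r`, `p_perm`, `n`.
#'   Correlations undefined because a variable is constant are reported
#'   as `NA`.
#' @export
validate_decorrelation <- function(results, n_perm = 10000L, seed = 1) {
  if (length(results) < 10L) stop_data("need at least 10 results")
  idx <- vapply(results, `[[`, numeric(1), "index")
  covs <- list(
    area = vapply(results, `[[`, numeric(1), "nucleus_area"),
    intensity_cv = vapply(results, `[[`, numeric(1), "nucleoplasm_intensity_cv"))
  perm_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    r_obs <- stats::cor(x, y)
    r_perm <- with_nm_seed(seed, {
      vapply(seq_len(n_perm), function(i) stats::cor(sample(x), y), numeric(1))
    })
    c(r = r_obs, p = (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1))
  }
  out <- do.call(rbind, lapply(names(covs), function(nm) {
    rc <- perm_cor(idx, covs[[nm]])
    data.frame(covariate = nm, r = rc[["r"]], p_perm = rc[["p"]],
               n = length(idx))
  }))
  out
}

#' @export
print.wrinkle_result <- function(x, ...) {
  cat(sprintf("Wrinkling index %.4g (area %.4g um^2, nucleoplasm CV %.3g, erosion %g px)\n",
              x$index, x$nucleus_area, x$nucleoplasm_intensity_cv, x$erosion_radius))
  invisible(x)
}
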