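# Nuclear morphometry: z-stack segmentation, nuclear volume, chromatin
# compaction index, 2D nucleus segmentation and per-nucleus intensities.

#' Construct a z-stack
#'
#' @param data 3D array of nonnegative intensities, dimensions (y, x, z).
#' @param voxel_xy Lateral pixel size in um.
#' @param z_step Axial step in um (default 0.3).
#' @return An object of class `zstack`.
#' @export
zstack <- function(data, voxel_xy, z_step = 0.3) {
  if (length(dim(data)) != 3L) stop_shape("zstack data must be a 3D array (y, x, z)")
  if (any(data < 0)) stop_data("intensities must be nonnegative")
  if (!is_scalar_num(z_step) || z_step <= 0) stop_invalid_parameter("z_step must be positive")
  if (!is_scalar_num(voxel_xy) || voxel_xy <= 0) stop_invalid_parameter("voxel_xy must be positive")
  structure(list(data = data, voxel_xy = voxel_xy, z_step = z_step),
            class = "zstack")
}

# Rescale to [0,1] by the data range (for threshold routines that expect it).
scale01 <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop_segmentation("empty foreground after thresholding")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  list(mask = lab == keep, n_components = length(sizes))
}

#' Segment the nucleus in a z-stack
#'
#' Maximum-intensity projection, Gaussian blur, global Otsu threshold, and
#' largest connected component give the projected nucleus mask (holes
#' filled). Per-slice masks are then derived inside the projected mask:
#' either by per-slice Otsu re-thresholding (default; the threshold is never
#' allowed below the whole-stack Otsu cut, which zeroes slices beyond the
#' nucleus) or by applying the projected mask to every slice as-is.
#'
#' @param stack A [zstack()].
#' @param blur_sigma Gaussian blur sigma in pixels (default 2).
#' @param threshold Threshold method; only `"otsu"` is implemented.
#' @param slice_method `"otsu"` (per-slice re-threshold) or `"projected"`.
#' @return An object of class `nucleus_mask3d`: projected mask, per-slice
#'   mask array, per-slice areas in um^2, and the projected component count.
#' @export
segment_stack <- function(stack, blur_sigma = 2, threshold = "otsu",
                          slice_method = c("otsu", "projected")) {
  stopifnot(inherits(stack, "zstack"))
  slice_method <- match.arg(slice_method)
  if (threshold != "otsu") stop_invalid_parameter("only the 'otsu' threshold method is implemented")
  d <- stack$data
  mip <- apply(d, c(1, 2), max)
  sc <- scale01(mip)
  if (all(sc == 0)) stop_segmentation("blank stack: no intensity variation")
  blurred <- EBImage::gblur(sc, sigma = blur_sigma)
  th <- EBImage::otsu(blurred, range = c(0, 1))
  comp <- largest_component(blurred > th)
  proj <- EBImage::fillHull(comp$mask) > 0

  nz <- dim(d)[3]
  in_mask_vals <- d[rep(proj, nz)]
  global_th <- EBImage::otsu(matrix(scale01(in_mask_vals), ncol = 1), range = c(0, 1)) *
    diff(range(in_mask_vals)) + min(in_mask_vals)
  slice_masks <- array(FALSE, dim(d))
  for (k in seq_len(nz)) {
    sl <- d[, , k]
    if (slice_method == "projected") {
      slice_masks[, , k] <- proj
    } else {
      v <- sl[proj]
      th_k <- if (diff(range(v)) > 0) {
        EBImage::otsu(matrix(scale01(v), ncol = 1), range = c(0, 1)) *
          diff(range(v)) + min(v)
      } else -Inf
      # an Otsu split isolating <1% of the in-mask pixels is unimodal noise
      # (slice fully inside, or fully beyond, the nucleus): use the global
      # threshold alone there
      frac <- mean(v > th_k)
      if (!is.finite(th_k) || frac < 0.01 || frac > 0.99) th_k <- -Inf
      slice_masks[, , k] <- proj & sl > max(th_k, global_th)
    }
  }
  areas <- apply(slice_masks, 3, sum) * stack$voxel_xy^2
  nucleus_mask3d(proj, slice_masks, areas, voxel_xy = stack$voxel_xy,
                 n_components = comp$n_components)
}

#' Construct a 3D nucleus mask
#'
#' @param projected Logical 2D projected mask.
#' @param slice_masks Logical 3D array of per-slice masks, each a subset of
#'   the projected mask.
#' @param slice_areas Per-slice areas in um^2.
#' @param voxel_xy Lateral pixel size in um.
#' @param n_components Number of connected components seen in the projection.
#' @return An object of class `nucleus_mask3d`.
#' @export
nucleus_mask3d <- function(projected, slice_masks, slice_areas = NULL,
                           voxel_xy = 1, n_components = 1L) {
  nz <- dim(slice_masks)[3]
  for (k in seq_len(nz)) {
    if (any(slice_masks[, , k] & !projected)) {
      stop_invalid_geometry("slice masks must be subsets of the projected mask")
    }
  }
  if (is.null(slice_areas)) slice_areas <- apply(slice_masks, 3, sum) * voxel_xy^2
  structure(list(projected = projected, slice_masks = slice_masks,
                 slice_areas = slice_areas, voxel_xy = voxel_xy,
                 n_components = n_components),
            class = "nucleus_mask3d")
}

#' Nuclear volume from per-slice areas
#'
#' The sum of the per-slice cross-section areas multiplied by the z-step.
#'
#' @param mask A [nucleus_mask3d()].
#' @param z_step Axial step in um.
#' @return Volume in um^3.
#' @export
nuclear_volume <- function(mask, z_step) {
  stopifnot(inherits(mask, "nucleus_mask3d"))
  sum(mask$slice_areas) * z_step
}

#' Chromatin compaction index
#'
#' The ratio of the integrated fluorescence intensity (sum over in-mask
#' voxels across all slices) to the nuclear volume. Lower values indicate
#' less condensed chromatin.
#'
#' @param stack The [zstack()] the mask was derived from.
#' @param mask A [nucleus_mask3d()].
#' @return An object of class `morphometry_result` with fields `volume`
#'   (um^3), `integrated_intensity` (a.u.) and `compaction_index`
#'   (a.u. per um^3), satisfying
#'   `compaction_index == integrated_intensity / volume` exactly.
#' @export
compaction_index <- function(stack, mask) {
  stopifnot(inherits(stack, "zstack"), inherits(mask, "nucleus_mask3d"))
  if (!identical(dim(stack$data), dim(mask$slice_masks))) {
    stop_shape("stack and mask dimensions differ")
  }
  vol <- nuclear_volume(mask, stack$z_step)
  if (vol <= 0) stop_degenerate("zero nuclear volume")
  integrated <- sum(stack$data[mask$slice_masks])
  structure(list(volume = vol, integrated_intensity = integrated,
                 compaction_index = integrated / vol),
            class = "morphometry_result")
}

#' Segment individual nuclei in a 2D image
#'
#' Gaussian blur, Otsu threshold, optional distance-transform watershed to
#' split touching nuclei, and a size filter. An image with no surviving
#' objects yields an all-zero label map, not an error.
#'
#' @param image 2D intensity matrix.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param min_area Minimum object area in um^2.
#' @param pixel_um Pixel size in um (default 1, i.e. `min_area` in px^2).
#' @param split Split touching objects by watershed (default `TRUE`).
#' @param watershed_tolerance Tolerance passed to [EBImage::watershed()].
#' @return Integer label matrix with labels 1..N.
#' @export
segment_nuclei_2d <- function(image, blur_sigma = 2, min_area = 0,
                              pixel_um = 1, split = TRUE,
                              watershed_tolerance = 1) {
  if (length(dim(image)) != 2L) stop_shape("image must be 2D")
  sc <- scale01(image)
  if (all(sc == 0)) return(matrix(0L, nrow(image), ncol(image)))
  blurred <- EBImage::gblur(sc, sigma = blur_sigma)
  mask <- blurred > EBImage::otsu(blurred, range = c(0, 1))
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  lab <- if (split) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = watershed_tolerance)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * pixel_um^2 >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Per-nucleus mean channel intensity
#'
#' Mean of a fluorescence channel over each labeled nucleus, e.g. to
#' quantify histone-mark staining per nucleus.
#'
#' @param labels Integer label matrix from [segment_nuclei_2d()].
#' @param channel 2D intensity matrix of the same shape.
#' @return Data frame with columns `label`, `mean_intensity`, `area_px`.
#' @export
per_nucleus_mean_intensity <- function(labels, channel) {
  if (!identical(dim(labels), dim(channel))) stop_shape("labels and channel shapes differ")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(0), mean_intensity = numeric(0),
                      area_px = integer(0)))
  }
  means <- vapply(ids, function(i) mean(channel[labels == i]), numeric(1))
  areas <- vapply(ids, function(i) sum(labels == i), integer(1))
  data.frame(label = ids, mean_intensity = means, area_px = areas)
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("Nuclear morphometry\n")
  cat(sprintf("  volume               : %.4g um^3\n", x$volume))
  cat(sprintf("  integrated intensity : %.6g a.u.\n", x$integrated_intensity))
  cat(sprintf("  compaction index     : %.4g a.u./um^3\n", x$compaction_index))
  invisible(x)
}
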