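# Z-stack segmentation, nuclear volume and chromatin compaction.

test_that("segment_stack recovers ellipse cross-sections within 5%", {
  st <- gen_nucleus_stack(semi_axes = c(5, 5, 3))
  mk <- segment_stack(st$stack)
  nz <- dim(st$stack$data)[3]
  z <- ((seq_len(nz) - 0.5) - nz / 2) * st$stack$z_step
  analytic <- ifelse(abs(z) < 3, pi * 25 * (1 - (z / 3)^2), 0)
  big <- analytic > 20  # compare away from the vanishing tip sections
  expect_true(all(abs(mk$slice_areas[big] - analytic[big]) / analytic[big] < 0.05))
  expect_equal(mk$n_components, 1L)
})

test_that("segment_stack fails on blank stacks and reports extra components", {
  blank <- zstack(array(0, c(20, 20, 4)), voxel_xy = 0.1)
  expect_error(segment_stack(blank), class = "segmentation_failure_error")

  # two well-separated nuclei: the largest-component rule keeps one
  dims <- c(60, 120, 12)
  wide <- array(10, dims)
  y <- ((seq_len(dims[1]) - 0.5) - dims[1] / 2) * 0.1
  z <- ((seq_len(dims[3]) - 0.5) - dims[3] / 2) * 0.3
  for (k in seq_len(dims[3])) {
    x <- ((seq_len(dims[2]) - 0.5)) * 0.1
    big_in <- outer((y / 2)^2, ((x - 3) / 2)^2, `+`) + (z[k] / 1.2)^2 <= 1
    sml_in <- outer((y / 1)^2, ((x - 9) / 1)^2, `+`) + (z[k] / 0.8)^2 <= 1
    sl <- wide[, , k]; sl[big_in | sml_in] <- 110; wide[, , k] <- sl
  }
  mk <- segment_stack(zstack(wide, voxel_xy = 0.1))
  expect_gte(mk$n_components, 2L)
  # kept object is the larger ellipsoid
  expect_equal(nuclear_volume(mk, 0.3), 4 / 3 * pi * 2 * 2 * 1.2, tolerance = 0.1)
})

test_that("nuclear_volume is the slice-area Riemann sum", {
  proj <- matrix(FALSE, 10, 10); proj[3:7, 3:7] <- TRUE
  slices <- array(FALSE, c(10, 10, 1)); slices[, , 1] <- proj
  mk <- nucleus_mask3d(proj, slices, slice_areas = 10, voxel_xy = 1)
  expect_equal(nuclear_volume(mk, 0.3), 3.0)

  st <- gen_nucleus_stack(semi_axes = c(5, 5, 3), z_step = 0.3)
  vol <- nuclear_volume(segment_stack(st$stack), 0.3)
  expect_equal(vol, 4 / 3 * pi * 75, tolerance = 0.05)
})

test_that("volume error shrinks monotonically with finer z-steps", {
  err <- vapply(c(0.6, 0.3, 0.15), function(zs) {
    st <- gen_nucleus_stack(semi_axes = c(5, 5, 3), z_step = zs)
    abs(nuclear_volume(segment_stack(st$stack), zs) - 4 / 3 * pi * 75) / (4 / 3 * pi * 75)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("compaction_index is integrated intensity over volume, exactly", {
  # handcrafted mask over a uniform field: voxel volume 1 um^3, intensity 100
  d <- array(100, c(6, 6, 4))
  st <- zstack(d, voxel_xy = 1, z_step = 1)
  proj <- matrix(TRUE, 6, 6)
  slices <- array(TRUE, c(6, 6, 4))
  mk <- nucleus_mask3d(proj, slices, voxel_xy = 1)
  res <- compaction_index(st, mk)
  expect_equal(res$compaction_index, 100)
  expect_identical(res$compaction_index, res$integrated_intensity / res$volume)

  # linear in global intensity; volume invariant to it
  st2 <- zstack(d * 2, voxel_xy = 1, z_step = 1)
  res2 <- compaction_index(st2, mk)
  expect_equal(res2$compaction_index, 2 * res$compaction_index)
  expect_equal(res2$volume, res$volume)
})

test_that("compaction_index depends only on the integrated intensity and volume", {
  st_u <- gen_nucleus_stack(interior_intensity = 100, texture = "uniform", seed = 3)
  st_c <- gen_nucleus_stack(interior_intensity = 100, texture = "clumped", seed = 3)
  mk <- segment_stack(st_u$stack, slice_method = "projected")
  r_u <- compaction_index(st_u$stack, mk)
  # rebuild the clumped stack to the same aggregates: rescale to equal sum in-mask
  d_c <- st_c$stack$data
  d_c <- d_c * sum(st_u$stack$data[mk$slice_masks]) / sum(d_c[mk$slice_masks])
  r_c <- compaction_index(zstack(d_c, 0.1, 0.3), mk)
  expect_equal(r_c$compaction_index, r_u$compaction_index, tolerance = 1e-12)
})

test_that("compaction_index is invariant under rigid translation of the nucleus", {
  st <- gen_nucleus_stack(semi_axes = c(3, 3, 2), margin = 2)
  d2 <- st$stack$data
  shift <- 8  # pixels
  d2 <- d2[c((shift + 1):dim(d2)[1], 1:shift), , ]
  r1 <- compaction_index(st$stack, segment_stack(st$stack))
  st2 <- zstack(d2, 0.1, 0.3)
  r2 <- compaction_index(st2, segment_stack(st2))
  expect_equal(r2$compaction_index, r1$compaction_index, tolerance = 1e-6)
  expect_equal(r2$volume, r1$volume, tolerance = 1e-6)
})

test_that("segment_nuclei_2d splits touching nuclei and filters by size", {
  img <- disk_image(80, 30, 40, 12) + disk_image(80, 48, 40, 12)
  img[img > 1] <- 1
  expect_equal(max(segment_nuclei_2d(img)), 2)
  expect_equal(max(segment_nuclei_2d(img, split = FALSE)), 1)

  expect_equal(max(segment_nuclei_2d(matrix(0, 50, 50))), 0)

  # a small disk below min_area is filtered out
  img2 <- disk_image(80, 20, 20, 12) + disk_image(80, 60, 60, 3)
  labs <- segment_nuclei_2d(img2, min_area = 100, split = FALSE)
  expect_equal(max(labs), 1)
})

test_that("per-nucleus means agree with the naive per-pixel oracle", {
  labs <- matrix(0L, 40, 40)
  labs[5:15, 5:15] <- 1L; labs[25:35, 20:30] <- 2L
  expect_true(all(per_nucleus_mean_intensity(labs, matrix(7, 40, 40))$mean_intensity == 7))
  expect_equal(per_nucleus_mean_intensity(labs, labs + 0)$mean_intensity, c(1, 2))

  set.seed(5)
  ch <- matrix(runif(1600), 40, 40)
  got <- per_nucleus_mean_intensity(labs, ch)
  expect_equal(got$mean_intensity, unname(naive_label_means(labs, ch)))
  expect_error(per_nucleus_mean_intensity(labs, matrix(0, 10, 10)), class = "shape_error")
})

test_that("generated stacks honor geometry and the seed contract", {
  g <- gen_nucleus_stack(semi_axes = c(5, 5, 3))
  expect_equal(g$truth$params$volume_um3, 4 / 3 * pi * 75)
  expect_error(gen_nucleus_stack(semi_axes = c(5, 5, 3), dims = c(30, 30, 5)),
               class = "invalid_geometry_error")

  # zero interior: stack equals background everywhere
  g0 <- gen_nucleus_stack(interior_intensity = 0, background = 10)
  expect_true(all(g0$stack$data == 10))

  a <- gen_nucleus_stack(noise_sd = 3, seed = 4)
  b <- gen_nucleus_stack(noise_sd = 3, seed = 4)
  expect_identical(a$stack$data, b$stack$data)
})
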