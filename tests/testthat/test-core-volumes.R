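test_that("voxel grids validate geometry and expose exact voxel volumes", {
  g <- vox_grid(array(0, c(96, 96, 64)), spacing = c(2.6, 2.6, 3.1))
  expect_equal(voxel_volume_ml(g), 2.6 * 2.6 * 3.1 / 1000)
  expect_equal(voxel_volume_ml(g), 0.020956, tolerance = 1e-12)
  expect_error(vox_grid(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "invalid geometry")
  expect_error(vox_grid(matrix(0, 4, 4)), "3-D array")
  g2 <- vox_grid(array(0, c(96, 96, 64)), spacing = c(2.6, 2.6, 3.1))
  expect_true(same_geometry(g, g2))
  expect_false(same_geometry(g, vox_grid(array(0, c(96, 96, 64)),
                                         spacing = c(2.1, 2.1, 2.0))))
})

test_that("resampling is exact for identity, constants and linear ramps", {
  set.seed(1)
  src <- vox_grid(array(rnorm(8 * 7 * 6), c(8, 7, 6)), spacing = c(2, 3, 4))
  expect_equal(resample_to(src, src)$values, src$values, tolerance = 1e-12)

  const <- new_like(src, 7)
  ref <- vox_grid(array(0, c(5, 5, 4)), spacing = c(1.5, 1.5, 2),
                  origin = c(-2, -2, -2))
  expect_true(all(abs(resample_to(const, ref)$values - 7) < 1e-12))

  # 2x downsample of a linear ramp: values must equal the linear function
  # evaluated at the new voxel centres (closed-form oracle)
  f <- function(x, y, z) 0.5 * x - 0.2 * y + 0.1 * z + 3
  ax <- grid_axes(src)
  vals <- outer(outer(0.5 * ax[[1]], -0.2 * ax[[2]], `+`), 0.1 * ax[[3]], `+`) + 3
  ramp <- new_like(src, vals)
  ref2 <- vox_grid(array(0, c(3, 3, 2)), spacing = src$spacing * 2,
                   origin = src$origin + src$spacing / 2)
  out <- resample_to(ramp, ref2)
  ax2 <- grid_axes(ref2)
  expected <- outer(outer(0.5 * ax2[[1]], -0.2 * ax2[[2]], `+`),
                    0.1 * ax2[[3]], `+`) + 3
  expect_equal(out$values, expected, tolerance = 1e-10)

  # nearest-neighbour keeps masks binary
  m <- new_like(src, array(runif(prod(dim(src))) > 0.5, dim(src$values)))
  out_m <- resample_to(m, ref, method = "nearest")
  expect_true(all(out_m$values %in% c(0, 1)))
})

test_that("SUV conversion is the documented linear scaling", {
  a <- vox_grid(array(5000, c(4, 4, 2)))
  s <- to_suv(a, dose_bq = 200e6, weight_g = 80000)
  expect_equal(s$grid$values[1, 1, 1], 2.0)
  expect_equal(to_suv(new_like(a, 0))$grid$values, array(0, c(4, 4, 2)))
  expect_error(to_suv(a, dose_bq = 0), "argument error")
  expect_error(to_suv(a, weight_g = -1), "argument error")

  # epsilon_rel computed from SUVs equals epsilon_rel from raw activities:
  # the dose/weight scaling cancels in the ratio
  set.seed(2)
  act1 <- vox_grid(array(runif(64, 1, 5), c(4, 4, 4)))
  act2 <- new_like(act1, act1$values * 0.7)
  mask <- array(TRUE, c(4, 4, 4))
  e_act <- epsilon_rel(mean(act2$values), mean(act1$values))
  s1 <- to_suv(act1, 150e6, 65e3); s2 <- to_suv(act2, 150e6, 65e3)
  e_suv <- epsilon_rel(roi_stats(s2, mask)$mean, roi_stats(s1, mask)$mean)
  expect_equal(e_suv, e_act, tolerance = 1e-12)
})

test_that("ROI statistics match a brute-force voxel loop", {
  g <- vox_grid(array(3.0, c(5, 5, 5)))
  m <- array(FALSE, c(5, 5, 5)); m[2:3, 2, 2] <- TRUE
  expect_equal(roi_stats(g, m), list(mean = 3, max = 3, n_voxels = 2))
  g$values[2, 2, 2] <- 1; g$values[3, 2, 2] <- 3
  expect_equal(roi_stats(g, m)$mean, 2)
  expect_equal(roi_stats(g, m)$max, 3)
  expect_error(roi_stats(g, array(FALSE, c(5, 5, 5))), "empty-ROI")

  set.seed(3)
  vol <- vox_grid(array(rnorm(20^3), c(20, 20, 20)))
  mask <- array(FALSE, c(20, 20, 20))
  mask[sample(20^3, 50)] <- TRUE
  st <- roi_stats(vol, mask)
  acc_sum <- 0; acc_max <- -Inf; n <- 0
  for (i in 1:20) for (j in 1:20) for (k in 1:20) if (mask[i, j, k]) {
    acc_sum <- acc_sum + vol$values[i, j, k]
    acc_max <- max(acc_max, vol$values[i, j, k])
    n <- n + 1
  }
  expect_equal(st$mean, acc_sum / n, tolerance = 1e-12)
  expect_equal(st$max, acc_max)
  expect_equal(st$n_voxels, 50L)
})

test_that("volumes and masks round-trip through NIfTI", {
  set.seed(4)
  g <- vox_grid(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(2.6, 2.6, 3.1),
                origin = c(-10, 5, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(g, path)
  g2 <- read_volume(path)
  expect_equal(g2$values, g$values, tolerance = 1e-7)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)

  m <- new_like(g, array(g$values > 0, dim(g$values)))
  pm <- tempfile(fileext = ".nii.gz")
  write_volume(m, pm, mask = TRUE)
  m2 <- read_volume(pm)
  expect_identical(array(m2$values != 0, dim(m$values)),
                   array(m$values != 0, dim(m$values)))
  unlink(c(path, pm))
})

test_that("YAML config supplies geometry and SUV scaling with defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  dim: [10, 12, 8]", "  spacing: [2.0, 2.0, 3.0]",
               "suv:", "  dose_bq: 1.5e8"), path)
  cfg <- read_config(path)
  expect_identical(dim(cfg$geometry$values), c(10L, 12L, 8L))
  expect_equal(cfg$geometry$spacing, c(2, 2, 3))
  expect_equal(cfg$suv$dose_bq, 1.5e8)
  expect_equal(cfg$suv$weight_g, 70e3)
  unlink(path)
})
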