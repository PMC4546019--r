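small_geom <- function(nz = 1L, n = 48L) {
  g <- vox_grid(array(0, c(n, n, nz)), spacing = c(2.6, 2.6, 3.1))
  proj_geom(g, n_angles = 40L, n_bins = 64L, bin_spacing_mm = 2.6)
}

test_that("attenuation factors follow the Beer-Lambert line integral", {
  geom <- small_geom()
  zero_mu <- mu_map(vox_grid(array(0, c(48, 48, 1)),
                             spacing = c(2.6, 2.6, 3.1)))
  expect_true(all(attenuation_factors(zero_mu, geom) == 1))

  # uniform disc, central ray: factor = exp(-mu * 2R), chord-length oracle
  disc <- disc_grid(n = 48, radius_mm = 40)
  geom_d <- proj_geom(disc, n_angles = 40L, n_bins = 64L, bin_spacing_mm = 2.6)
  f <- attenuation_factors(mu_map(disc), geom_d)
  central_bin <- which.min(abs(geom_d$radial))
  expected <- exp(-0.1 * 2 * 4.0)   # R = 4 cm
  measured <- f[central_bin, 1, 1]
  expect_lt(abs(measured - expected) / expected, 0.005)

  # a less attenuating map gives larger factors everywhere
  half <- mu_map(new_like(disc, disc$values / 2))
  expect_true(all(attenuation_factors(half, geom_d) >=
                    attenuation_factors(mu_map(disc), geom_d) - 1e-12))

  neg <- vox_grid(array(-1, c(48, 48, 1)), spacing = c(2.6, 2.6, 3.1))
  expect_error(mu_map(neg), "domain error")
})

test_that("forward projection is linear and traces point-source sinusoids", {
  geom <- small_geom()
  zero <- vox_grid(array(0, c(48, 48, 1)), spacing = c(2.6, 2.6, 3.1))
  expect_true(all(forward_project(zero, NULL, geom)$prompts == 0))

  set.seed(5)
  act <- new_like(zero, array(runif(48 * 48), c(48, 48, 1)))
  s1 <- forward_project(act, NULL, geom)
  s2 <- forward_project(new_like(act, 2 * act$values), NULL, geom)
  expect_equal(s2$prompts, 2 * s1$prompts, tolerance = 1e-12)

  # point source at radius r, azimuth phi: the sinogram trace peaks at
  # radial position r cos(theta - phi)
  src <- new_like(zero, 0)
  ax <- grid_axes(src)
  ix <- 33L; iy <- 18L
  src$values[ix, iy, 1] <- 1
  x0 <- ax[[1]][ix]; y0 <- ax[[2]][iy]
  r0 <- sqrt(x0^2 + y0^2); phi0 <- atan2(y0, x0)
  sp <- forward_project(src, NULL, geom)
  for (a in seq(1, geom$n_angles, by = 7)) {
    peak <- which.max(sp$prompts[, a, 1])
    s_pred <- r0 * cos(geom$angles[a] - phi0)
    expect_lt(abs(geom$radial[peak] - s_pred), 1.5 * geom$bin_spacing_mm)
  }
})

test_that("Poisson sampling is seeded and unbiased", {
  geom <- small_geom()
  zero <- sinogram_set(array(0, c(64, 40, 1)), array(1, c(64, 40, 1)), 0, geom)
  expect_true(all(sample_counts(zero, 1)$prompts == 0))

  const <- sinogram_set(array(50, c(64, 40, 4)), array(1, c(64, 40, 4)), 0,
                        geom)
  draw <- sample_counts(const, seed = 123)
  n <- length(draw$prompts)   # 10240 independent draws at expectation 50
  expect_lt(abs(mean(draw$prompts) - 50), 3 * sqrt(50 / n))
  expect_identical(sample_counts(const, seed = 123)$prompts, draw$prompts)
  expect_false(identical(sample_counts(const, seed = 124)$prompts,
                         draw$prompts))
})

test_that("forward and back projectors are exact adjoints", {
  geom <- small_geom()
  sm <- muinpaint:::system_matrix(geom)
  set.seed(6)
  x <- rnorm(ncol(sm$A)); y <- rnorm(nrow(sm$A))
  lhs <- sum((sm$A %*% x) * y)
  rhs <- sum(x * (sm$At %*% y))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("MLEM recovers a uniform disc and OSEM reproduces the AC bias sign", {
  disc_mu <- disc_grid(n = 48, radius_mm = 40)
  geom <- proj_geom(disc_mu, n_angles = 40L, n_bins = 64L, bin_spacing_mm = 2.6)
  act <- new_like(disc_mu, (disc_mu$values > 0.05) * 1.0)
  expected <- forward_project(act, mu_map(disc_mu), geom)

  # noiseless MLEM with the true mu-map: interior mean within 2%
  rec <- reconstruct_osem(expected, mu_map(disc_mu),
                          recon_params(n_iterations = 20, n_subsets = 1,
                                       postfilter_fwhm_mm = 0))
  interior <- muinpaint:::erode6(disc_mu$values > 0.99 * 0.1, 2L)
  expect_lt(abs(mean(rec$values[interior]) - 1), 0.02)

  # AC with a void-bearing map underestimates activity inside the void
  mu_void <- new_like(disc_mu, disc_mu$values)
  void <- array(FALSE, dim(mu_void$values)); void[20:28, 20:28, 1] <- TRUE
  mu_void$values[void] <- 0
  rp <- recon_params(n_iterations = 3, n_subsets = 8, postfilter_fwhm_mm = 4)
  rec_void <- reconstruct_osem(expected, mu_map(mu_void), rp)
  rec_true <- reconstruct_osem(expected, mu_map(disc_mu), rp)
  expect_lt(mean(rec_void$values[void]), mean(rec_true$values[void]))

  # all-zero counts collapse to an all-zero image; updates stay nonnegative
  zero_sino <- sinogram_set(array(0, dim(expected$prompts)),
                            expected$att_factors, 0, geom)
  rec0 <- reconstruct_osem(zero_sino, mu_map(disc_mu), rp)
  expect_true(all(rec0$values == 0))
  expect_true(all(rec_void$values >= 0))
})

test_that("MLEM increases the Poisson likelihood and conserves counts", {
  disc_mu <- disc_grid(n = 32, radius_mm = 28)
  geom <- proj_geom(disc_mu, n_angles = 30L, n_bins = 44L, bin_spacing_mm = 2.6)
  act <- new_like(disc_mu, (disc_mu$values > 0.05) * 1.0)
  sino <- sample_counts(forward_project(act, mu_map(disc_mu), geom), seed = 9)

  lls <- numeric(6)
  for (it in seq_along(lls)) {
    r <- reconstruct_osem(sino, mu_map(disc_mu),
                          recon_params(n_iterations = it, n_subsets = 1,
                                       postfilter_fwhm_mm = 0))
    lls[it] <- poisson_loglik(sino, r, mu_map(disc_mu))
  }
  expect_true(all(diff(lls) > -1e-6 * abs(lls[1])))

  # stationarity: after convergence total forward-projected counts match
  # the measured counts within 0.5% (no background, no filter)
  r50 <- reconstruct_osem(sino, mu_map(disc_mu),
                          recon_params(n_iterations = 50, n_subsets = 1,
                                       postfilter_fwhm_mm = 0))
  sm <- muinpaint:::system_matrix(geom)
  f <- attenuation_factors(mu_map(disc_mu), geom)
  ybar <- as.vector(f) * as.vector(sm$A %*% as.vector(r50$values))
  expect_lt(abs(sum(ybar) - sum(sino$prompts)) / sum(sino$prompts), 0.005)
})

test_that("sinograms round-trip through NIfTI with their geometry sidecar", {
  geom <- small_geom()
  set.seed(7)
  sino <- sinogram_set(array(rpois(64 * 40, 20), c(64, 40, 1)),
                       array(1, c(64, 40, 1)), 0.5, geom)
  path <- tempfile(fileext = ".nii.gz")
  write_sinogram(sino, path)
  back <- read_sinogram(path)
  expect_equal(back$prompts, sino$prompts, tolerance = 1e-7)
  expect_equal(back$geometry$n_angles, geom$n_angles)
  expect_equal(back$geometry$radial, geom$radial)
  expect_equal(back$background, 0.5)
  unlink(c(path, paste0(path, ".json")))
})
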