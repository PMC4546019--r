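test_that("atlas means behave like arithmetic means", {
  ph <- base_phantom()
  atlas1 <- build_atlas(list(ph$water))
  expect_identical(atlas1$mean_water$values, ph$water$values)
  expect_identical(atlas1$n_subjects, 1L)
  expect_error(build_atlas(list()), "argument error")

  pop <- make_population(phantom_spec(), 3, seed = 55)
  ws <- lapply(pop, function(p) p$water)
  a3 <- build_atlas(ws)
  # adding a duplicated subject equals the reweighted mean
  a4 <- build_atlas(c(ws, ws[3]))
  expected <- (3 * a3$mean_water$values + ws[[3]]$values) / 4
  expect_equal(a4$mean_water$values, expected, tolerance = 1e-12)
})

test_that("the population template matches the generator's dental region", {
  atlas <- stock_atlas()
  ph <- make_phantom(phantom_spec(jitter_sd_mm = 0))
  d <- muinpaint:::dice(atlas$oral_cavity_mask, ph$dental_region)
  expect_gte(d, 0.8)
  # the template lies inside the head and excludes the sinuses
  expect_true(all(atlas$inside[atlas$oral_cavity_mask]))
  expect_lt(sum(atlas$oral_cavity_mask & ph$sinus_mask) /
              sum(ph$sinus_mask), 0.05)
})

test_that("registration recovers identity and known translations", {
  atlas <- stock_atlas()
  tr_id <- register_to_atlas(atlas$mean_water, atlas)
  expect_lt(max(abs(tr_id$par[1:3])), 0.1)          # mm
  expect_lt(max(abs(tr_id$par[4:6])) * 180 / pi, 0.1)  # degrees

  # patient = atlas shifted by (5, -3, 2) mm
  shifted <- resample_to(atlas$mean_water,
                         vox_grid(array(0, dim(atlas$mean_water$values)),
                                  atlas$mean_water$spacing,
                                  atlas$mean_water$origin - c(5, -3, 2)))
  shifted <- vox_grid(shifted$values, atlas$mean_water$spacing,
                      atlas$mean_water$origin)
  tr <- register_to_atlas(shifted, atlas)
  # the patient anatomy sits at +(5, -3, 2), so the patient-to-atlas
  # transform is the inverse translation
  expect_lt(max(abs(tr$par[1:3] + c(5, -3, 2))), 0.5)

  # registration of a phantom with a large outer artifact still converges
  ph <- inject_artifact(base_phantom(), artifact_spec("outer", 160, seed = 61))
  tro <- register_to_atlas(ph$water, atlas)
  expect_true(tro$converged)
  expect_lt(max(abs(tro$par[1:3])), 8)
})

test_that("the 80%/10% fill policy is exactly threshold-consistent", {
  # synthetic mu with four separate 100-voxel void slabs inside tissue
  d <- c(40, 40, 12)
  v <- array(0, d)
  v[3:38, 3:38, 2:11] <- MU_SOFT_TISSUE
  comps <- list(c(4, 13, 4, 13), c(4, 13, 16, 25), c(16, 25, 4, 13),
                c(16, 25, 16, 25))
  for (cc in comps) v[cc[1]:cc[2], cc[3]:cc[4], 4] <- 0  # 100 voxels each
  mu <- mu_map(vox_grid(v, spacing = c(1, 1, 1)))
  voids <- detect_voids(mu)
  expect_identical(nrow(voids$components), 4L)

  idx <- array(seq_len(prod(d)), d)
  overlap_mask <- function(n_overlap_per_comp) {
    m <- array(FALSE, d)
    for (i in seq_along(comps)) {
      cc <- comps[[i]]
      k <- n_overlap_per_comp[i]
      if (k > 0) m[idx[cc[1]:cc[2], cc[3]:cc[4], 4][seq_len(k)]] <- TRUE
    }
    m
  }

  # canonical fractions 0.85 / 0.50 / 0.05 plus an exact-threshold case
  mask <- overlap_mask(c(85, 50, 5, 80))
  res <- fill_masked_voids(mu, voids, mask_patient = mask,
                           anatomical_threshold = Inf)
  rep <- res$report[order(res$report$id), ]
  frac_of <- function(f) rep$action[abs(rep$fraction - f) < 1e-9]
  expect_identical(frac_of(0.85), "completed")
  expect_identical(frac_of(0.50), "kept_partial")
  expect_identical(frac_of(0.05), "reversed")
  expect_identical(frac_of(0.80), "kept_partial")   # strict threshold

  # behaviour flips exactly across 0.80 and 0.10
  mask2 <- overlap_mask(c(81, 79, 10, 9))
  res2 <- fill_masked_voids(mu, voids, mask_patient = mask2,
                            anatomical_threshold = Inf)
  rep2 <- res2$report
  expect_identical(rep2$action[abs(rep2$fraction - 0.81) < 1e-9], "completed")
  expect_identical(rep2$action[abs(rep2$fraction - 0.79) < 1e-9], "kept_partial")
  expect_identical(rep2$action[abs(rep2$fraction - 0.10) < 1e-9], "kept_partial")
  expect_identical(rep2$action[abs(rep2$fraction - 0.09) < 1e-9], "reversed")

  # actions change the map exactly as documented
  comp_full <- muinpaint:::component_mask(
    voids, rep$id[abs(rep$fraction - 0.85) < 1e-9])
  expect_true(all(res$mu$grid$values[comp_full] == MU_SOFT_TISSUE))
  comp_rev <- muinpaint:::component_mask(
    voids, rep$id[abs(rep$fraction - 0.05) < 1e-9])
  expect_true(all(res$mu$grid$values[comp_rev] == 0))
  comp_part <- muinpaint:::component_mask(
    voids, rep$id[abs(rep$fraction - 0.50) < 1e-9])
  expect_identical(sum(res$mu$grid$values[comp_part] == MU_SOFT_TISSUE), 50L)

  expect_error(fill_policy(complete_threshold = 0.5, reverse_threshold = 0.6),
               "argument error")
})

test_that("inpainting fills inner voids via the template and protects sinuses", {
  atlas <- stock_atlas()
  ph <- inject_artifact(base_phantom(), artifact_spec("inner", 6, seed = 11))
  sim <- simulate_case(ph, seed = 71)
  ip <- inpaint(ph$mu_dixon, sim$pet_nac, ph$water, atlas)
  vt <- ph$void_truth
  restored <- sum(ip$changed_mask & vt) / sum(vt)
  expect_gt(restored, 0.7)
  # monotone, and only adds attenuation
  expect_true(all(ip$mu_inpainted$grid$values >= ph$mu_dixon$grid$values))
  # sinuses stay air
  expect_true(all(ip$mu_inpainted$grid$values[ph$sinus_mask] == 0))
  expect_identical(ip$mu_inpainted$provenance, "inpainted")
})
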