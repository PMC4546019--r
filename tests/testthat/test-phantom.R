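test_that("phantom generation is deterministic and internally consistent", {
  spec <- phantom_spec(seed = 9L)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$mu_truth$grid$values, p2$mu_truth$grid$values)
  expect_identical(p1$water$values, p2$water$values)
  expect_identical(p1$activity$values, p2$activity$values)

  # invariants
  expect_true(all(p1$mu_truth$grid$values >= 0))
  expect_true(all(p1$mu_truth$grid$values[p1$cavity_mask] == 0))
  expect_true(all(p1$mu_truth$grid$values[p1$sinus_mask] == 0))
  soft <- p1$mu_truth$grid$values == MU_SOFT_TISSUE
  expect_true(any(soft))
  expect_true(all(p1$activity$values[p1$body_mask &
                                       p1$mu_truth$grid$values > 0] > 0))
  expect_true(all(p1$activity$values[!p1$body_mask] == 0))
})

test_that("oral cavity voxel volume matches the analytic ellipsoid volume", {
  spec <- phantom_spec(jitter_sd_mm = 0)
  ph <- make_phantom(spec)
  vml <- voxel_volume_ml(ph$activity)
  realized <- sum(ph$cavity_mask) * vml
  analytic <- 4 / 3 * pi * prod(spec$oral_semi) / 1000
  # tolerance: one voxel shell over the ellipsoid surface
  shell <- muinpaint:::dilate6(ph$cavity_mask) & !ph$cavity_mask
  expect_lt(abs(realized - analytic), sum(shell) * vml)
})

test_that("body mask equals the flood-fill definition of the solid body", {
  ph <- base_phantom()
  # solid = non-air voxels plus internal cavities, via a border flood fill
  air <- ph$mu_truth$grid$values == 0
  outside <- muinpaint:::flood_from_border(air)
  solid_oracle <- !air | (air & !outside)
  expect_identical(muinpaint:::fill_holes(ph$body_mask), solid_oracle)
})

test_that("injected artifacts realize their target volumes and classes", {
  ph <- base_phantom()
  vml <- voxel_volume_ml(ph$activity)

  p_in <- inject_artifact(ph, artifact_spec("inner", 6, seed = 11))
  v_in <- sum(p_in$void_truth) * vml
  expect_gte(v_in, 5.1); expect_lte(v_in, 6.9)
  # flood-fill oracle: inner void not reachable from background air
  air <- p_in$mu_dixon$grid$values < 0.005
  reach <- muinpaint:::flood_from_border(air)
  expect_false(any(reach & p_in$void_truth))
  # one-voxel dilation stays inside the body
  expect_true(all(muinpaint:::fill_holes(ph$body_mask)[
    muinpaint:::dilate6(p_in$void_truth, 1L)]))

  p_out <- inject_artifact(ph, artifact_spec("outer", 133, seed = 12))
  v_out <- sum(p_out$void_truth) * vml
  expect_gte(v_out, 113); expect_lte(v_out, 153)
  air_o <- p_out$mu_dixon$grid$values < 0.005
  reach_o <- muinpaint:::flood_from_border(air_o)
  expect_true(any(reach_o & p_out$void_truth))

  # identity for a zero-volume request
  expect_identical(inject_artifact(ph, artifact_spec("inner", 0))$mu_dixon,
                   ph$mu_dixon)

  # voids only remove attenuation, never add it
  expect_true(all(p_out$mu_dixon$grid$values <= p_out$mu_truth$grid$values))
})

test_that("the generator supports the full observed void-volume range", {
  ph <- base_phantom()
  vml <- voxel_volume_ml(ph$activity)
  lo <- inject_artifact(ph, artifact_spec("inner", 1.6, seed = 5))
  hi <- inject_artifact(ph, artifact_spec("outer", 520.8, seed = 15))
  expect_lt(abs(sum(lo$void_truth) * vml - 1.6), 0.15 * 1.6)
  expect_lt(abs(sum(hi$void_truth) * vml - 520.8), 0.15 * 520.8)
  # reproducible per seed
  lo2 <- inject_artifact(ph, artifact_spec("inner", 1.6, seed = 5))
  expect_identical(lo$void_truth, lo2$void_truth)
  # over-capacity request fails loudly
  expect_error(inject_artifact(ph, artifact_spec("inner", 400, seed = 1)),
               "spec error")
})

test_that("phantom populations jitter independently and average smoothly", {
  spec <- phantom_spec(seed = 13L)
  spec0 <- phantom_spec(seed = 13L, jitter_sd_mm = 0)
  one <- make_population(spec0, 1, seed = 13L)[[1]]
  ref <- make_phantom(phantom_spec(seed = one$spec$seed, jitter_sd_mm = 0))
  expect_identical(one$mu_truth$grid$values, ref$mu_truth$grid$values)

  popA <- make_population(spec, 6, seed = 101)
  popB <- make_population(spec, 6, seed = 202)
  expect_false(identical(popA[[1]]$water$values, popB[[1]]$water$values))
  expect_false(identical(popA[[1]]$body_mask, popA[[2]]$body_mask))

  # the voxelwise mean water image is smoother than any single member
  meanw <- Reduce(`+`, lapply(popA, function(p) p$water$values)) / 6
  tv_mean <- total_variation(meanw)
  tv_members <- vapply(popA, function(p) total_variation(p$water$values),
                       numeric(1))
  expect_true(all(tv_mean < tv_members))

  expect_error(make_population(spec, 0), "argument error")
})
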