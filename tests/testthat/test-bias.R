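test_that("relative and absolute differences follow their definitions", {
  expect_equal(epsilon_rel(1.0, 1.0), 0)
  expect_equal(epsilon_rel(0, 2.5), -100)   # total loss of PET activity
  expect_equal(epsilon_rel(0.5, 1.0), -50)
  expect_warning(expect_equal(epsilon_rel(0, 0), 0), "0/0")
  expect_error(epsilon_rel(1, 0), "undefined error")

  expect_equal(epsilon_abs(1, 1), 0)
  expect_error(epsilon_abs(-1, 1), "argument error")

  # the reported lesion pair: mean absolute difference -1 together with mean
  # relative difference -19% back-solves to SUVs 4.26 / 5.26
  expect_equal(epsilon_abs(4.26, 5.26), -1)
  expect_equal(epsilon_rel(4.26, 5.26), -100 / 5.26, tolerance = 1e-12)
  expect_equal(round(epsilon_rel(4.26, 5.26)), -19)

  # same sign whenever the denominator is positive
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0, 4); b <- runif(1, 0.1, 4)
    expect_equal(sign(epsilon_rel(a, b)), sign(epsilon_abs(a, b)))
  }
})

test_that("ROI reports apply the formulas to both statistics", {
  set.seed(12)
  g <- vox_grid(array(runif(16^3, 0.5, 3), c(16, 16, 16)))
  masks <- list(tongue = array(FALSE, c(16, 16, 16)),
                cerebellum = array(FALSE, c(16, 16, 16)))
  masks$tongue[2:5, 2:5, 2:5] <- TRUE
  masks$cerebellum[10:14, 10:14, 10:14] <- TRUE
  rois <- roi_set(masks, g)

  r_same <- roi_report(g, g, rois)
  expect_true(all(r_same$eps_rel_mean == 0))
  expect_true(all(r_same$eps_abs_max == 0))

  half <- new_like(g, g$values * 0.5)
  r_half <- roi_report(half, g, rois)
  expect_true(all(abs(r_half$eps_rel_mean + 50) < 1e-9))
  expect_true(all(abs(r_half$eps_rel_max + 50) < 1e-9))

  # the relative and absolute metrics stay algebraically linked
  expect_equal(r_half$eps_rel_mean,
               100 * r_half$eps_abs_mean / r_half$suv_mean_inpainted,
               tolerance = 1e-12)
})

test_that("difference images are NaN-free and follow the voxel rules", {
  gi <- vox_grid(array(2, c(6, 6, 2)))
  gd <- new_like(gi, gi$values)
  di <- difference_images(gd, gi)
  expect_true(all(di$rel$values == 0) && all(di$abs$values == 0))

  gd2 <- new_like(gi, gi$values); gd2$values[1, 1, 1] <- 0
  di2 <- difference_images(gd2, gi)
  expect_equal(di2$rel$values[1, 1, 1], -100)

  gi3 <- new_like(gi, gi$values); gi3$values[2, 2, 2] <- 0
  gd3 <- new_like(gi, gi$values)
  di3 <- difference_images(gd3, gi3)
  expect_false(any(is.nan(di3$rel$values)))
  expect_identical(attr(di3$rel, "n_undefined"), 1L)

  # mask-integrated absolute differences reproduce the mask-level relative
  # difference when combined consistently
  set.seed(13)
  a <- vox_grid(array(runif(8^3, 1, 3), c(8, 8, 8)))
  b <- new_like(a, array(runif(8^3, 1, 3), c(8, 8, 8)))
  mask <- array(runif(8^3) > 0.5, c(8, 8, 8))
  d <- difference_images(a, b)
  lhs <- mean(d$abs$values[mask]) / mean(b$values[mask]) * 100
  rhs <- epsilon_rel(mean(a$values[mask]), mean(b$values[mask]))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the signed-rank test matches enumeration and the stats oracle", {
  # six all-negative differences: exact two-sided p = 2/2^6
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 3, 4, 5, 6, 7)
  w <- wilcoxon_matched(x, y)
  expect_equal(w$p_value, 2 / 64)
  expect_identical(w$method, "exact")

  # antisymmetric pairs sit at the null centre
  d <- c(0.5, -0.5, 1.2, -1.2)
  wa <- wilcoxon_matched(d, rep(0, 4))
  expect_equal(wa$p_value, 1)

  # all-zero differences degenerate
  wz <- wilcoxon_matched(c(1, 2), c(1, 2))
  expect_true(wz$degenerate)

  set.seed(14)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n, 0, 2), 2); y <- round(rnorm(n, 0.3, 2), 2)
    if (all(x == y)) next
    w <- wilcoxon_matched(x, y)
    expect_equal(w$p_value, signrank_enum_p(x, y), tolerance = 1e-12)
    d <- x - y; d <- d[d != 0]
    if (!anyDuplicated(abs(d))) {
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
    }
  }

  # normal approximation stays within 0.01 of enumeration at n = 15
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(15, 0.4)
    w <- wilcoxon_matched(x, y)
    expect_lt(abs(w$p_value - signrank_enum_p(x, y)), 0.01)
    # under ties the normal approximation is used
    wt <- wilcoxon_matched(round(x, 1), round(y, 1))
    expect_true(wt$method %in% c("exact signed-rank", "normal approximation"))
  }
})

test_that("cohort summaries reduce reports with the documented statistics", {
  mk_report <- function(eps, vol, cls) {
    df <- data.frame(roi = c("tongue", "inpainted_area"),
                     suv_mean_dixon = 1, suv_mean_inpainted = 1,
                     suv_max_dixon = 1, suv_max_inpainted = 1,
                     eps_rel_mean = eps, eps_rel_max = eps / 2,
                     eps_abs_mean = 0, eps_abs_max = 0,
                     n_voxels = 10L, error = NA_character_)
    attr(df, "artifact_volume_ml") <- vol
    attr(df, "artifact_class") <- cls
    class(df) <- c("bias_report", "data.frame")
    df
  }
  one <- cohort_summary(list(mk_report(c(-5, -50), 10, "inner")))
  expect_equal(one$table$eps_rel_mean_avg[one$table$roi == "inpainted_area"],
               -50)
  expect_equal(one$table$eps_rel_mean_sd, c(0, 0))

  reports <- list(mk_report(c(-4, -40), 10, "outer"),
                  mk_report(c(-6, -55), 50, "outer"),
                  mk_report(c(-8, -70), 120, "outer"))
  cs <- cohort_summary(reports)
  row <- cs$table[cs$table$roi == "inpainted_area", ]
  vals <- c(-40, -55, -70)
  expect_equal(row$eps_rel_mean_avg, mean(vals))
  expect_equal(row$eps_rel_mean_sd, sd(vals))   # sample std (n-1)
  expect_equal(c(row$eps_rel_mean_min, row$eps_rel_mean_max), range(vals))
  expect_equal(unname(cs$spearman_volume_bias["outer"]), 1)
  expect_error(cohort_summary(list()), "argument error")
})

test_that("distance shells summarize bias by distance from the void", {
  set.seed(16)
  d <- c(24, 24, 8)
  void <- array(FALSE, d); void[11:14, 11:14, 4:5] <- TRUE
  body <- array(TRUE, d)
  gi <- vox_grid(array(2, d))
  # bias decays with distance from the void
  dist <- muinpaint:::distance_mm(void, c(1, 1, 1))
  gd <- new_like(gi, gi$values * (1 - 0.5 * exp(-dist / 5)))
  sh <- distance_shells(gd, gi, void, body, edges_mm = c(0, 3, 6, 10, 15))
  expect_true(all(diff(sh$eps_rel_mean) > 0))   # toward 0 with distance
  expect_true(all(sh$n_voxels > 0))
})
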