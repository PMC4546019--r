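# Quantification of the attenuation-correction bias: relative and absolute
# SUV differences between the reconstruction with the uncorrected map
# (PET_DIXON) and with the inpainted map (PET_INPAINTED), ROI reports,
# difference images, distance shells, Wilcoxon matched-pairs testing and
# cohort summaries.

#' Relative SUV difference (percent)
#'
#' `(suv_dixon - suv_inpainted) / suv_inpainted * 100`. A value of -100%
#' marks a total loss of PET activity in the uncorrected reconstruction.
#'
#' @param suv_dixon,suv_inpainted scalar SUVs (>= 0).
#' @return percent difference.
#' @export
epsilon_rel <- function(suv_dixon, suv_inpainted) {
  if (suv_inpainted == 0) {
    if (suv_dixon == 0) {
      warning("epsilon_rel: 0/0 defined as 0", call. = FALSE)
      return(0)
    }
    stop("undefined error: suv_inpainted = 0 with suv_dixon > 0", call. = FALSE)
  }
  (suv_dixon - suv_inpainted) / suv_inpainted * 100
}

#' Absolute SUV difference
#'
#' `suv_dixon - suv_inpainted`, in SUV units.
#'
#' @param suv_dixon,suv_inpainted scalar SUVs (>= 0).
#' @return SUV difference.
#' @export
epsilon_abs <- function(suv_dixon, suv_inpainted) {
  if (suv_dixon < 0 || suv_inpainted < 0)
    stop("argument error: SUVs must be >= 0", call. = FALSE)
  suv_dixon - suv_inpainted
}

#' Per-ROI bias report between the two reconstructions
#'
#' Computes mean and max SUV of both images per ROI and the relative (Eq.-
#' style percent) and absolute differences on both statistics. The
#' `inpainted_area` ROI should be the set of voxels changed by the
#' correction; pass it inside `rois` or via `inpainted_mask`.
#'
#' @param pet_dixon,pet_inpainted `suv_map` (or [vox_grid()]) reconstructions.
#' @param rois a [roi_set()].
#' @param inpainted_mask optional logical array appended as the
#'   `inpainted_area` ROI.
#' @param voids optional [detect_voids()] result; its largest component's
#'   volume and class annotate the report.
#' @return object of class `bias_report`: a data.frame with one row per ROI
#'   (`roi`, `suv_mean_dixon`, `suv_mean_inpainted`, `suv_max_dixon`,
#'   `suv_max_inpainted`, `eps_rel_mean`, `eps_rel_max`, `eps_abs_mean`,
#'   `eps_abs_max`, `n_voxels`, `error`), with attributes `artifact_volume_ml`
#'   and `artifact_class`.
#' @export
roi_report <- function(pet_dixon, pet_inpainted, rois, inpainted_mask = NULL,
                       voids = NULL) {
  gd <- as_grid(pet_dixon); gi <- as_grid(pet_inpainted)
  stop_if_incompatible(gd, gi, "the two PET images")
  masks <- as.list(rois)
  names(masks) <- names(rois)
  if (!is.null(inpainted_mask)) masks$inpainted_area <- inpainted_mask
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m != 0)) {
      return(data.frame(roi = nm, suv_mean_dixon = NA_real_,
                        suv_mean_inpainted = NA_real_,
                        suv_max_dixon = NA_real_, suv_max_inpainted = NA_real_,
                        eps_rel_mean = NA_real_, eps_rel_max = NA_real_,
                        eps_abs_mean = NA_real_, eps_abs_max = NA_real_,
                        n_voxels = 0L, error = "empty ROI"))
    }
    sd_ <- roi_stats(gd, m)
    si_ <- roi_stats(gi, m)
    data.frame(roi = nm,
               suv_mean_dixon = sd_$mean, suv_mean_inpainted = si_$mean,
               suv_max_dixon = sd_$max, suv_max_inpainted = si_$max,
               eps_rel_mean = epsilon_rel(sd_$mean, si_$mean),
               eps_rel_max = epsilon_rel(sd_$max, si_$max),
               eps_abs_mean = epsilon_abs(sd_$mean, si_$mean),
               eps_abs_max = epsilon_abs(sd_$max, si_$max),
               n_voxels = sd_$n_voxels, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(voids) && nrow(voids$components)) {
    attr(out, "artifact_volume_ml") <- sum(voids$components$volume_ml)
    attr(out, "artifact_class") <-
      if (any(voids$components$class == "outer")) "outer" else "inner"
  }
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Voxelwise relative and absolute difference images
#'
#' Relative differences use the same convention as [epsilon_rel()]; voxels
#' where both images are 0 are reported as 0, and voxels where only the
#' inpainted image is 0 (undefined ratio) are set to 0 and counted in the
#' `"n_undefined"` attribute. Outputs are NaN-free.
#'
#' @param pet_dixon,pet_inpainted the two reconstructions.
#' @return list of two [vox_grid()]: `rel` (percent) and `abs` (SUV).
#' @export
difference_images <- function(pet_dixon, pet_inpainted) {
  gd <- as_grid(pet_dixon); gi <- as_grid(pet_inpainted)
  stop_if_incompatible(gd, gi, "the two PET images")
  ab <- gd$values - gi$values
  rel <- array(0, dim(ab))
  pos <- gi$values > 0
  rel[pos] <- 100 * ab[pos] / gi$values[pos]
  n_undef <- sum(!pos & gd$values > 0)
  out_rel <- new_like(gd, rel)
  attr(out_rel, "n_undefined") <- n_undef
  list(rel = out_rel, abs = new_like(gd, ab))
}

#' Wilcoxon signed-rank test for matched pairs
#'
#' Two-sided test on paired differences. Zero differences are discarded; for
#' `n <= 12` remaining pairs the p-value is computed from the exact
#' permutation null (all 2^n sign assignments, valid under ties via
#' midranks); for larger tie-free samples from the exact signed-rank
#' distribution, and under ties from the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y paired measurements (e.g. SUV_mean under the two corrections),
#'   or `y = NULL` and `x` a two-column matrix.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`, `n`
#'   (non-zero pairs), `method`, and `degenerate` (TRUE when all differences
#'   are zero).
#' @export
wilcoxon_matched <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  if (length(x) != length(y) || length(x) < 1L)
    stop("argument error: need matched pairs", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 12L) {
    # exact permutation null: all sign assignments of the observed |d| ranks
    stats_all <- exact_signrank_stats(r)
    # two-sided p: as extreme as V in either direction around the centre
    centre <- sum(r) / 2
    p <- mean(abs(stats_all - centre) >= abs(V - centre) - 1e-9)
    list(statistic = V, p_value = min(1, p), n = n, method = "exact",
         degenerate = FALSE)
  } else if (!anyDuplicated(abs(d))) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(n * (n + 1) / 2 - V, n)))
    list(statistic = V, p_value = p, n = n, method = "exact signed-rank",
         degenerate = FALSE)
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    list(statistic = V, p_value = min(1, p), n = n,
         method = "normal approximation", degenerate = FALSE)
  }
}

# all 2^n values of the positive-rank sum over sign assignments
exact_signrank_stats <- function(ranks) {
  n <- length(ranks)
  stats_all <- 0
  for (i in seq_len(n)) {
    stats_all <- c(stats_all, stats_all + ranks[i])
  }
  stats_all
}

#' Cohort summary of per-phantom bias reports
#'
#' Mean, sample standard deviation (n-1) and range of the relative
#' differences across phantoms, per ROI and artifact class, plus the
#' volume-versus-bias table and its Spearman rank correlation (between void
#' volume and |eps_rel_mean| of the inpainted area).
#'
#' @param reports list of [roi_report()] results (each annotated with
#'   `artifact_volume_ml` / `artifact_class` attributes, as produced by the
#'   pipeline).
#' @return object of class `cohort_summary`: list with `table` (per
#'   class/ROI: `eps_rel_mean_avg`, `eps_rel_mean_sd`, `eps_rel_mean_min/max`,
#'   same for `eps_rel_max`, `n`), `volume_bias` (per phantom) and
#'   `spearman_volume_bias` (per class).
#' @export
cohort_summary <- function(reports) {
  if (!length(reports)) stop("argument error: no reports", call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    cbind(phantom = i, as.data.frame(r),
          volume_ml = attr(r, "artifact_volume_ml") %||% NA_real_,
          class = attr(r, "artifact_class") %||% NA_character_)
  }))
  long <- long[is.na(long$error), ]
  sd1 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  tab <- do.call(rbind, lapply(split(long, list(long$class, long$roi),
                                     drop = TRUE), function(gr) {
    data.frame(class = gr$class[1], roi = gr$roi[1], n = nrow(gr),
               eps_rel_mean_avg = mean(gr$eps_rel_mean),
               eps_rel_mean_sd = sd1(gr$eps_rel_mean),
               eps_rel_mean_min = min(gr$eps_rel_mean),
               eps_rel_mean_max = max(gr$eps_rel_mean),
               eps_rel_max_avg = mean(gr$eps_rel_max),
               eps_rel_max_sd = sd1(gr$eps_rel_max),
               eps_rel_max_min = min(gr$eps_rel_max),
               eps_rel_max_max = max(gr$eps_rel_max))
  }))
  rownames(tab) <- NULL
  vb <- long[long$roi == "inpainted_area",
             c("phantom", "class", "volume_ml", "eps_rel_mean")]
  sp <- vapply(split(vb, vb$class), function(gr) {
    if (nrow(gr) < 3 || !all(is.finite(gr$volume_ml))) return(NA_real_)
    stats::cor(gr$volume_ml, abs(gr$eps_rel_mean), method = "spearman")
  }, numeric(1))
  structure(list(table = tab, volume_bias = vb, spearman_volume_bias = sp),
            class = "cohort_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print cohort_summary
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$table)
  cat("Spearman volume vs |eps_rel_mean| (inpainted area):\n")
  print(x$spearman_volume_bias)
  invisible(x)
}

#' Bias versus distance from the void
#'
#' Mean relative difference in concentric Euclidean-distance shells from the
#' void mask, an explicit operationalization of the distance dependence of
#' the SUV underestimation.
#'
#' @param pet_dixon,pet_inpainted the two reconstructions.
#' @param void_mask logical array (e.g. the true or detected void).
#' @param body_mask logical array restricting the shells to the body.
#' @param edges_mm shell edges in mm.
#' @return data.frame with `shell_lo_mm`, `shell_hi_mm`, `eps_rel_mean`,
#'   `n_voxels`.
#' @export
distance_shells <- function(pet_dixon, pet_inpainted, void_mask, body_mask,
                            edges_mm = c(0, 10, 20, 30, 50, 80, 120)) {
  gd <- as_grid(pet_dixon); gi <- as_grid(pet_inpainted)
  dmap <- distance_mm(void_mask, gd$spacing)
  rows <- lapply(seq_len(length(edges_mm) - 1), function(i) {
    sel <- dmap >= edges_mm[i] & dmap < edges_mm[i + 1] & body_mask &
      !void_mask & gi$values > 0
    if (!any(sel))
      return(data.frame(shell_lo_mm = edges_mm[i], shell_hi_mm = edges_mm[i + 1],
                        eps_rel_mean = NA_real_, n_voxels = 0L))
    data.frame(shell_lo_mm = edges_mm[i], shell_hi_mm = edges_mm[i + 1],
               eps_rel_mean = epsilon_rel(mean(gd$values[sel]),
                                          mean(gi$values[sel])),
               n_voxels = sum(sel))
  })
  do.call(rbind, rows)
}

#' Write a bias report (or cohort summary) as CSV / JSON
#'
#' @param x a `bias_report` or `cohort_summary`.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return invisibly `x`.
#' @export
write_report <- function(x, path_csv = NULL, path_json = NULL) {
  df <- if (inherits(x, "cohort_summary")) x$table else as.data.frame(x)
  if (!is.null(path_csv)) utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(df, path_json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(x)
}
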