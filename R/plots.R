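# Minimal base-graphics visualization helpers for QC.

#' Display one axial slice of a volume
#'
#' @param grid a [vox_grid()] (or `mu_map`/`suv_map`).
#' @param z slice index (default: middle slice).
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @return invisibly the slice matrix.
#' @export
plot_slice <- function(grid, z = NULL, main = NULL, ...) {
  g <- as_grid(grid)
  if (is.null(z)) z <- ceiling(dim(g$values)[3] / 2)
  ax <- grid_axes(g)
  sl <- g$values[, , z]
  graphics::image(ax[[1]], ax[[2]], sl, asp = 1, xlab = "x [mm]",
                  ylab = "y [mm]", main = main %||% sprintf("slice z=%d", z),
                  col = grDevices::gray.colors(128, 0, 1), ...)
  invisible(sl)
}

#' Plot a per-ROI bias report
#'
#' Horizontal bars of the relative mean-SUV difference per ROI.
#'
#' @param x a [roi_report()] result.
#' @param ... unused.
#' @export
plot.bias_report <- function(x, ...) {
  ok <- is.na(x$error)
  graphics::barplot(x$eps_rel_mean[ok], names.arg = x$roi[ok], horiz = TRUE,
                    las = 1, xlab = "relative difference of SUV mean [%]",
                    main = "attenuation-correction bias per ROI")
  graphics::abline(v = 0)
  invisible(x)
}

#' Plot volume versus bias for a cohort
#'
#' @param x a [cohort_summary()] result.
#' @param ... unused.
#' @export
plot.cohort_summary <- function(x, ...) {
  vb <- x$volume_bias
  graphics::plot(vb$volume_ml, abs(vb$eps_rel_mean),
                 pch = ifelse(vb$class == "outer", 17, 16),
                 xlab = "artifact volume [mL]",
                 ylab = "|relative difference of SUV mean| [%]",
                 main = "bias vs artifact volume (inpainted area)")
  graphics::legend("topleft", legend = c("inner", "outer"), pch = c(16, 17))
  invisible(x)
}
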