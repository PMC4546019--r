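#' Attenuation map (mu-map)
#'
#' A [vox_grid()] of linear attenuation coefficients at 511 keV in cm^-1
#' (all values >= 0), an optional binary body mask (the anatomical envelope),
#' and a provenance tag. The soft-tissue fill constant used everywhere in the
#' package is exactly 0.1 cm^-1 (`MU_SOFT_TISSUE`).
#'
#' @param grid [vox_grid()] with non-negative values in cm^-1.
#' @param body_mask optional logical/0-1 array, same shape as `grid$values`.
#' @param provenance one of `"dixon"`, `"inpainted"`, `"truth"`.
#' @return object of class `mu_map`.
#' @export
mu_map <- function(grid, body_mask = NULL,
                   provenance = c("dixon", "inpainted", "truth")) {
  provenance <- match.arg(provenance)
  if (!inherits(grid, "vox_grid")) stop("`grid` must be a vox_grid", call. = FALSE)
  if (any(grid$values < 0))
    stop("domain error: mu-map values must be >= 0", call. = FALSE)
  if (!is.null(body_mask)) {
    if (!identical(dim(body_mask), dim(grid$values)))
      stop("geometry error: body_mask shape mismatch", call. = FALSE)
    body_mask <- array(body_mask != 0, dim(grid$values))
  }
  structure(list(grid = grid, body_mask = body_mask, provenance = provenance),
            class = "mu_map")
}

#' @export
#' @method print mu_map
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map> provenance=%s, body_mask=%s\n", x$provenance,
              if (is.null(x$body_mask)) "none" else
                sprintf("%d voxels", sum(x$body_mask))))
  print(x$grid)
  invisible(x)
}

#' Soft-tissue linear attenuation coefficient (cm^-1)
#'
#' The constant used to inpaint signal voids.
#' @export
MU_SOFT_TISSUE <- 0.1

#' Convert an activity-concentration volume to SUV
#'
#' SUV = concentration (Bq/mL) * body weight (g) / injected dose (Bq). The
#' operation is linear and order-preserving; all relative bias metrics in the
#' package are invariant to the scaling.
#'
#' @param activity [vox_grid()] of activity concentration (Bq/mL), values >= 0.
#' @param dose_bq injected dose in Bq (> 0). Default 200 MBq.
#' @param weight_g body weight in g (> 0). Default 70 kg.
#' @return object of class `suv_map` with fields `grid` (dimensionless SUV)
#'   and `scaling`.
#' @examples
#' a <- vox_grid(array(5000, c(4, 4, 2)))
#' s <- to_suv(a, dose_bq = 200e6, weight_g = 80000)
#' s$grid$values[1, 1, 1]  # 2.0
#' @export
to_suv <- function(activity, dose_bq = 200e6, weight_g = 70e3) {
  if (!is.finite(dose_bq) || dose_bq <= 0 || !is.finite(weight_g) || weight_g <= 0)
    stop("argument error: dose_bq and weight_g must be positive", call. = FALSE)
  g <- new_like(activity, activity$values * weight_g / dose_bq)
  structure(list(grid = g, scaling = list(dose_bq = dose_bq, weight_g = weight_g)),
            class = "suv_map")
}

#' @export
#' @method print suv_map
print.suv_map <- function(x, ...) {
  cat(sprintf("<suv_map> dose %.3g Bq, weight %.3g g\n",
              x$scaling$dose_bq, x$scaling$weight_g))
  print(x$grid)
  invisible(x)
}

as_grid <- function(x) {
  if (inherits(x, "vox_grid")) x
  else if (inherits(x, c("suv_map", "mu_map"))) x$grid
  else stop("expected a vox_grid, suv_map or mu_map", call. = FALSE)
}

#' ROI statistics of an SUV map
#'
#' Arithmetic mean and maximum of the image over the voxels of a binary mask.
#'
#' @param suv a `suv_map` (or plain [vox_grid()]).
#' @param mask logical/0-1 array geometry-compatible with the image; must be
#'   non-empty.
#' @return list with `mean`, `max`, `n_voxels`.
#' @export
roi_stats <- function(suv, mask) {
  g <- as_grid(suv)
  if (inherits(mask, "vox_grid")) {
    stop_if_incompatible(g, mask, "SUV image and ROI mask")
    mask <- mask$values
  }
  if (!identical(dim(mask), dim(g$values)))
    stop("geometry error: mask shape mismatch", call. = FALSE)
  sel <- which(mask != 0)
  if (length(sel) == 0L) stop("empty-ROI error: mask has no voxels", call. = FALSE)
  v <- g$values[sel]
  list(mean = mean(v), max = max(v), n_voxels = length(sel))
}

#' Named set of reference ROIs
#'
#' A named list of binary masks sharing one geometry. Canonical names used by
#' the phantom and reporting code: `tongue`, `lower_tongue`,
#' `masticatory_muscles` (union of left and right), `cerebellum`, and
#' `inpainted_area` (attached by the evaluation step).
#'
#' @param masks named list of logical arrays of identical shape, each
#'   non-empty.
#' @param geometry [vox_grid()] the masks live on.
#' @return object of class `roi_set` (a named list of logical arrays with a
#'   `geometry` attribute).
#' @export
roi_set <- function(masks, geometry) {
  stopifnot(is.list(masks), length(names(masks)) == length(masks))
  d <- dim(geometry$values)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop(sprintf("geometry error: ROI '%s' shape mismatch", nm), call. = FALSE)
    if (!any(masks[[nm]] != 0))
      stop(sprintf("empty-ROI error: ROI '%s' is empty", nm), call. = FALSE)
    masks[[nm]] <- array(masks[[nm]] != 0, d)
  }
  structure(masks, geometry = geometry, class = "roi_set")
}

#' @export
#' @method print roi_set
print.roi_set <- function(x, ...) {
  cat("<roi_set>", paste(sprintf("%s(%d)", names(x), vapply(x, sum, 0)),
                         collapse = ", "), "\n")
  invisible(x)
}
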