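#' 3-D voxel grid
#'
#' The basic volumetric container used throughout the package: a 3-D numeric
#' array together with its voxel spacing and the world coordinates of the
#' centre of voxel (1,1,1). Axis order is fixed as (x, y, z) and the world
#' mapping is `world = origin + (index - 1) * spacing` (no rotation).
#'
#' @param values numeric 3-D array (nx, ny, nz).
#' @param spacing numeric length-3, voxel spacing in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre. Default centres the grid on the world origin.
#' @return An object of class `vox_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- vox_grid(array(0, c(8, 8, 4)), spacing = c(2.6, 2.6, 3.1))
#' voxel_volume_ml(g)
#' @export
vox_grid <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid geometry: spacing must be 3 positive numbers", call. = FALSE)
  if (is.null(origin)) origin <- -(dim(values) - 1) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("invalid geometry: origin must be 3 finite numbers", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vox_grid")
}

#' @export
#' @method print vox_grid
print.vox_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vox_grid> %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.vox_grid <- function(x) dim(x$values)

#' Voxel volume in millilitres
#'
#' @param grid a [vox_grid()] (or anything with a `spacing` field).
#' @return `prod(spacing) / 1000`, the voxel volume in mL.
#' @export
voxel_volume_ml <- function(grid) {
  sp <- if (inherits(grid, "vox_grid")) grid$spacing else grid$grid$spacing
  prod(sp) / 1000
}

#' Test geometry compatibility of two grids
#'
#' Two grids are geometry-compatible iff shape, spacing and origin are all
#' equal (spacing/origin to within 1e-6 mm). All voxelwise operations in the
#' package require compatibility.
#'
#' @param a,b [vox_grid()] objects.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

stop_if_incompatible <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry error: %s are not geometry-compatible", what),
         call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of voxel centres along each axis
#' @param grid a [vox_grid()].
#' @return list of three numeric vectors (x, y, z) in mm.
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(i) grid$origin[i] + (seq_len(d[i]) - 1) * grid$spacing[i])
}

#' Build a grid with the same geometry as another
#'
#' @param grid a [vox_grid()] supplying the geometry.
#' @param values scalar or array recycled to the grid's shape.
#' @return a [vox_grid()] geometry-compatible with `grid`.
#' @export
new_like <- function(grid, values) {
  vox_grid(array(values, dim(grid$values)), grid$spacing, grid$origin)
}

#' Resample a grid onto a reference geometry
#'
#' Interpolates `src` at the voxel centres of `ref`. Scalar fields use
#' trilinear interpolation; masks should use nearest-neighbour to stay binary.
#' Points outside the source extent evaluate to 0.
#'
#' @param src source [vox_grid()].
#' @param ref reference [vox_grid()] supplying the target geometry (its values
#'   are ignored).
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return a [vox_grid()] geometry-compatible with `ref`.
#' @export
resample_to <- function(src, ref, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(ref$values)
  ax <- grid_axes(ref)
  # continuous (1-based) source indices of every target voxel centre
  ix <- (ax[[1]] - src$origin[1]) / src$spacing[1] + 1
  iy <- (ax[[2]] - src$origin[2]) / src$spacing[2] + 1
  iz <- (ax[[3]] - src$origin[3]) / src$spacing[3] + 1
  out <- interp3(src$values, ix, iy, iz, method)
  vox_grid(array(out, d), ref$spacing, ref$origin)
}

# Trilinear / nearest interpolation of a 3-D array on the tensor grid of
# continuous indices (ix, iy, iz); outside -> 0. Returns an array.
interp3 <- function(vals, ix, iy, iz, method = "trilinear") {
  d <- dim(vals)
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  IX <- array(rep(ix, times = ny * nz), c(nx, ny, nz))
  IY <- array(rep(rep(iy, each = nx), times = nz), c(nx, ny, nz))
  IZ <- array(rep(iz, each = nx * ny), c(nx, ny, nz))
  interp3_points(vals, as.vector(IX), as.vector(IY), as.vector(IZ), method,
                 dim_out = c(nx, ny, nz))
}

# Interpolate at arbitrary continuous index triples (vectors of equal length).
interp3_points <- function(vals, ix, iy, iz, method = "trilinear",
                           dim_out = NULL) {
  d <- dim(vals)
  if (method == "nearest") {
    jx <- round(ix); jy <- round(iy); jz <- round(iz)
    ok <- jx >= 1 & jx <= d[1] & jy >= 1 & jy <= d[2] & jz >= 1 & jz <= d[3]
    out <- numeric(length(ix))
    idx <- (pmin(pmax(jx, 1), d[1])) +
      (pmin(pmax(jy, 1), d[2]) - 1) * d[1] +
      (pmin(pmax(jz, 1), d[3]) - 1) * d[1] * d[2]
    out[ok] <- vals[idx[ok]]
  } else {
    x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
    fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
    out <- numeric(length(ix))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      jx <- x0 + dx; jy <- y0 + dy; jz <- z0 + dz
      ok <- w > 0 & jx >= 1 & jx <= d[1] & jy >= 1 & jy <= d[2] &
        jz >= 1 & jz <= d[3]
      if (any(ok)) {
        idx <- jx[ok] + (jy[ok] - 1) * d[1] + (jz[ok] - 1) * d[1] * d[2]
        out[ok] <- out[ok] + w[ok] * vals[idx]
      }
    }
  }
  if (!is.null(dim_out)) dim(out) <- dim_out
  out
}

#' Read / write volumes as NIfTI-1
#'
#' Volumes round-trip through the NIfTI affine: spacing via `pixdim`, origin
#' via the translation column. Masks are written as uint8 \{0,1\}.
#'
#' @param grid a [vox_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask logical; write as uint8 mask.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [vox_grid()].
#' @export
write_volume <- function(grid, path, mask = FALSE) {
  vals <- grid$values
  if (mask) {
    vals <- array(as.integer(vals != 0), dim(vals))
  }
  # NIfTI affine: diagonal spacing, translation = origin
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  datatype <- if (mask) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)   # single-slice volumes drop a dim
  vox_grid(array(as.numeric(img), d[1:3]), spacing, origin)
}

#' Load a grid geometry or SUV scaling from a YAML config
#'
#' Reads a YAML file with optional entries `geometry: {dim, spacing, origin}`
#' and `suv: {dose_bq, weight_g}` and returns them as a list; missing entries
#' take the package defaults (the mu-map geometry of the simulated scanner and
#' 200 MBq / 70 kg).
#'
#' @param path YAML file path.
#' @return list with elements `geometry` (a zero-filled [vox_grid()]) and
#'   `suv` (list of `dose_bq`, `weight_g`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- cfg$geometry
  dim <- if (!is.null(geom$dim)) as.integer(geom$dim) else c(96L, 96L, 64L)
  spacing <- if (!is.null(geom$spacing)) as.numeric(geom$spacing) else c(2.6, 2.6, 3.1)
  origin <- if (!is.null(geom$origin)) as.numeric(geom$origin) else NULL
  suv <- list(
    dose_bq = if (!is.null(cfg$suv$dose_bq))
      as.numeric(cfg$suv$dose_bq) else 200e6,
    weight_g = if (!is.null(cfg$suv$weight_g))
      as.numeric(cfg$suv$weight_g) else 70e3
  )
  list(geometry = vox_grid(array(0, dim), spacing, origin), suv = suv)
}
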