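# 2-D parallel-beam attenuated projection simulator and OP-OSEM
# reconstruction, slice-by-slice along z. The forward model is an explicit
# sparse system matrix (line integrals with trilinear in-plane sampling), so
# the back projector is its exact transpose.

.geom_cache <- new.env(parent = emptyenv())

#' Parallel-beam projection geometry
#'
#' Defines the 2-D (per axial slice) parallel-beam sinogram sampling bound to
#' an image grid. Angles span `[0, pi)`; the radial extent must cover the
#' imaged object.
#'
#' @param image_grid [vox_grid()] whose in-plane geometry the projector is
#'   built for (values ignored).
#' @param n_angles number of projection angles over `[0, pi)`; must be
#'   divisible by the OSEM subset count used later. Default 126 (= 6 x 21).
#' @param n_bins number of radial bins.
#' @param bin_spacing_mm radial bin spacing (mm).
#' @param step_factor ray sampling step as a fraction of the in-plane voxel
#'   size (the line-integral quadrature step).
#' @return object of class `proj_geom`.
#' @export
proj_geom <- function(image_grid, n_angles = 126L, n_bins = 128L,
                      bin_spacing_mm = 2.6, step_factor = 0.5) {
  stopifnot(inherits(image_grid, "vox_grid"))
  n_angles <- as.integer(n_angles); n_bins <- as.integer(n_bins)
  if (n_angles < 1L || n_bins < 1L)
    stop("invalid geometry: n_angles and n_bins must be >= 1", call. = FALSE)
  structure(list(
    dim = dim(image_grid$values), spacing = image_grid$spacing,
    origin = image_grid$origin,
    n_angles = n_angles, n_bins = n_bins,
    bin_spacing_mm = bin_spacing_mm, step_factor = step_factor,
    angles = (seq_len(n_angles) - 1) * pi / n_angles,
    radial = (seq_len(n_bins) - (n_bins + 1) / 2) * bin_spacing_mm
  ), class = "proj_geom")
}

#' @export
#' @method print proj_geom
print.proj_geom <- function(x, ...) {
  cat(sprintf("<proj_geom> %d angles x %d bins (%.3g mm), image %d x %d x %d\n",
              x$n_angles, x$n_bins, x$bin_spacing_mm,
              x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

geom_key <- function(geom) {
  paste(c(geom$dim[1:2], signif(geom$spacing[1:2], 10),
          signif(geom$origin[1:2], 10), geom$n_angles, geom$n_bins,
          signif(geom$bin_spacing_mm, 10), signif(geom$step_factor, 10)),
        collapse = "|")
}

# Build (and cache) the in-plane sparse system matrix A (rays x voxels).
# Entry (r, v) approximates the intersection length (cm) of ray r with the
# bilinear footprint of voxel v; ray index r = (angle-1)*n_bins + bin.
system_matrix <- function(geom) {
  key <- geom_key(geom)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)

  nx <- geom$dim[1]; ny <- geom$dim[2]
  sx <- geom$spacing[1]; sy <- geom$spacing[2]
  ox <- geom$origin[1]; oy <- geom$origin[2]
  h <- geom$step_factor * min(sx, sy)            # quadrature step, mm
  half_len <- sqrt((nx * sx)^2 + (ny * sy)^2) / 2 + h
  u <- seq(-half_len, half_len, by = h)
  nb <- geom$n_bins

  blocks <- vector("list", geom$n_angles)
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    # ray: p(u) = s*(cos th, sin th) + u*(-sin th, cos th)
    px <- outer(geom$radial * cos(th), -sin(th) * u, `+`)  # nb x nu (mm)
    py <- outer(geom$radial * sin(th),  cos(th) * u, `+`)
    ix <- (px - ox) / sx + 1                                # continuous index
    iy <- (py - oy) / sy + 1
    x0 <- floor(ix); y0 <- floor(iy)
    fx <- ix - x0; fy <- iy - y0
    ray <- rep(seq_len(nb), times = length(u))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (dx in 0:1) for (dy in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
      jxv <- x0 + dx; jyv <- y0 + dy
      ok <- jxv >= 1 & jxv <= nx & jyv >= 1 & jyv <= ny & w > 0
      if (any(ok)) {
        ii <- c(ii, ray[ok])
        jj <- c(jj, jxv[ok] + (jyv[ok] - 1) * nx)
        xx <- c(xx, w[ok] * h / 10)  # mm -> cm path length
      }
    }
    blocks[[a]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                        dims = c(nb, nx * ny))
  }
  A <- do.call(rbind, blocks)
  obj <- list(A = A, At = Matrix::t(A))
  .geom_cache[[key]] <- obj
  obj
}

# Subset structure: bit-reversal interleaved angle ordering.
bit_reverse_order <- function(n) {
  # permutation of 0:(n-1) by reversed binary representation, stable for any n
  bits <- ceiling(log2(max(n, 2)))
  idx <- 0:(n - 1)
  rev <- vapply(idx, function(v) {
    r <- 0L
    for (b in seq_len(bits)) { r <- r * 2L + v %% 2L; v <- v %/% 2L }
    r
  }, integer(1))
  order(rev)
}

subset_rows <- function(geom, n_subsets) {
  if (geom$n_angles %% n_subsets != 0L)
    stop("argument error: n_subsets must divide n_angles", call. = FALSE)
  ord <- bit_reverse_order(n_subsets)
  lapply(ord, function(s) {
    ang <- seq(s, geom$n_angles, by = n_subsets)
    as.vector(outer(seq_len(geom$n_bins), (ang - 1) * geom$n_bins, `+`))
  })
}

#' Attenuation factors of a mu-map
#'
#' Per-ray survival probabilities `exp(-integral mu dl)` with `mu` in cm^-1
#' and path length in cm; values in (0, 1], equal to 1 where no attenuating
#' material lies along the ray.
#'
#' @param mu a [mu_map()] (geometry must match the projector's image grid).
#' @param geom a [proj_geom()].
#' @return numeric array `(n_bins, n_angles, nz)`.
#' @export
attenuation_factors <- function(mu, geom) {
  g <- as_grid(mu)
  if (any(g$values < 0)) stop("domain error: mu must be >= 0", call. = FALSE)
  check_geom_image(geom, g)
  sm <- system_matrix(geom)
  nz <- dim(g$values)[3]
  M <- matrix(g$values, ncol = nz)
  f <- exp(-as.matrix(sm$A %*% M))
  array(f, c(geom$n_bins, geom$n_angles, nz))
}

check_geom_image <- function(geom, grid) {
  if (!identical(geom$dim, dim(grid$values)) ||
      any(abs(geom$spacing - grid$spacing) > 1e-6) ||
      any(abs(geom$origin - grid$origin) > 1e-6))
    stop("geometry error: image grid does not match projection geometry",
         call. = FALSE)
  invisible(TRUE)
}

#' Sinogram container
#'
#' Projection-domain data bound to a [proj_geom()]: prompt counts (or
#' expected values), attenuation factors, and a flat expected-background term
#' (scatter/randoms surrogate).
#'
#' @param prompts array `(n_bins, n_angles, nz)`, >= 0.
#' @param att_factors array like `prompts` with values in (0, 1].
#' @param background scalar or array, expected background per bin (>= 0).
#' @param geometry a [proj_geom()].
#' @return object of class `sinogram_set`.
#' @export
sinogram_set <- function(prompts, att_factors, background = 0, geometry) {
  if (any(prompts < 0)) stop("domain error: prompts must be >= 0", call. = FALSE)
  structure(list(prompts = prompts, att_factors = att_factors,
                 background = background, geometry = geometry),
            class = "sinogram_set")
}

#' @export
#' @method print sinogram_set
print.sinogram_set <- function(x, ...) {
  cat(sprintf("<sinogram_set> %d x %d x %d, total counts %.4g, background %s\n",
              dim(x$prompts)[1], dim(x$prompts)[2], dim(x$prompts)[3],
              sum(x$prompts),
              if (length(x$background) == 1) format(x$background) else "array"))
  invisible(x)
}

#' Forward-project an activity map through an attenuating medium
#'
#' Expected prompts = attenuation factors x line integrals of activity plus a
#' flat background. Linear in the activity. The background is parameterized
#' as a fraction of the mean attenuated true coincidence rate.
#'
#' @param activity [vox_grid()] of non-negative activity.
#' @param mu [mu_map()] used for the attenuation factors (`NULL` for none).
#' @param geom [proj_geom()].
#' @param background_fraction flat background as a fraction of the mean
#'   attenuated trues (>= 0, default 0).
#' @return a [sinogram_set()] of expected values.
#' @export
forward_project <- function(activity, mu = NULL, geom,
                            background_fraction = 0) {
  check_geom_image(geom, activity)
  if (any(activity$values < 0))
    stop("domain error: activity must be >= 0", call. = FALSE)
  sm <- system_matrix(geom)
  nz <- dim(activity$values)[3]
  P <- as.matrix(sm$A %*% matrix(activity$values, ncol = nz))
  f <- if (is.null(mu)) array(1, c(geom$n_bins, geom$n_angles, nz))
       else attenuation_factors(mu, geom)
  trues <- array(f, dim = dim(f)) * array(P, dim = dim(f))
  b <- if (background_fraction > 0) background_fraction * mean(trues) else 0
  sinogram_set(trues + b, f, b, geom)
}

#' Poisson realization of an expected sinogram
#'
#' Independent Poisson draws per bin; deterministic per seed.
#'
#' @param expected a [sinogram_set()] of expected values.
#' @param seed integer seed.
#' @return a [sinogram_set()] of integer counts (same factors/background).
#' @export
sample_counts <- function(expected, seed = 1L) {
  if (any(expected$prompts < 0))
    stop("domain error: expectation must be >= 0", call. = FALSE)
  counts <- with_seed(seed, stats::rpois(length(expected$prompts),
                                         expected$prompts))
  sinogram_set(array(counts, dim(expected$prompts)), expected$att_factors,
               expected$background, expected$geometry)
}

#' Reconstruction parameters
#'
#' Defaults follow the simulated protocol: 3 iterations, 21 subsets, 4-mm
#' Gaussian post filter (sigma = FWHM / 2.3548, in-plane and axial).
#'
#' @param n_iterations OSEM iterations (>= 1).
#' @param n_subsets subsets (>= 1, must divide the angle count).
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM in mm (0 disables).
#' @param background_fraction flat scatter-surrogate fraction used when the
#'   sinogram itself carries no background (rarely needed; the sinogram's own
#'   term wins).
#' @return object of class `recon_params`.
#' @export
recon_params <- function(n_iterations = 3L, n_subsets = 21L,
                         postfilter_fwhm_mm = 4.0, background_fraction = 0) {
  if (n_iterations < 1L || n_subsets < 1L || postfilter_fwhm_mm < 0)
    stop("argument error: invalid reconstruction parameters", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 background_fraction = background_fraction),
            class = "recon_params")
}

#' Ordinary-Poisson OSEM reconstruction
#'
#' Multiplicative OSEM with the attenuation factors of `mu_for_ac` in the
#' system model and the sinogram's expected background in the denominator.
#' Initialization is uniform over the scanner field of view; voxels with zero
#' sensitivity are excluded from updates (and reported via the
#' `"n_zero_sensitivity"` attribute). The Gaussian post filter is applied
#' last. Output is non-negative at every update.
#'
#' @param sino a [sinogram_set()] of counts.
#' @param mu_for_ac [mu_map()] used for attenuation correction (`NULL` for an
#'   uncorrected, NAC, reconstruction).
#' @param params a [recon_params()].
#' @return activity [vox_grid()] on the projector's image grid.
#' @export
reconstruct_osem <- function(sino, mu_for_ac = NULL,
                             params = recon_params()) {
  geom <- sino$geometry
  sm <- system_matrix(geom)
  rows <- subset_rows(geom, params$n_subsets)
  nz <- dim(sino$prompts)[3]
  nvox <- prod(geom$dim[1:2])
  nray <- geom$n_bins * geom$n_angles

  F <- if (is.null(mu_for_ac)) matrix(1, nray, nz)
       else matrix(attenuation_factors(mu_for_ac, geom), nray, nz)
  Y <- matrix(sino$prompts, nray, nz)

  # field-of-view support: voxels seen by the full system with nonzero
  # attenuation-weighted sensitivity
  sens_full <- as.matrix(sm$At %*% F)
  support <- sens_full > 1e-10
  X <- matrix(0, nvox, nz)
  X[support] <- 1
  n_zero <- sum(!support)

  As <- lapply(rows, function(r) sm$A[r, , drop = FALSE])
  Ats <- lapply(As, Matrix::t)

  for (it in seq_len(params$n_iterations)) {
    for (s in seq_along(rows)) {
      r <- rows[[s]]
      Fs <- F[r, , drop = FALSE]
      Ys <- Y[r, , drop = FALSE]
      bs <- if (length(sino$background) == 1L) sino$background
            else matrix(sino$background, nray, nz)[r, , drop = FALSE]
      sens <- as.matrix(Ats[[s]] %*% Fs)
      denom <- Fs * as.matrix(As[[s]] %*% X) + bs
      ratio <- Fs * Ys / pmax(denom, 1e-12)
      ratio[Ys == 0] <- 0
      back <- as.matrix(Ats[[s]] %*% ratio)
      upd <- back / pmax(sens, 1e-12)
      upd[sens <= 1e-12] <- 0
      X <- X * upd
    }
  }

  vals <- array(X, c(geom$dim[1], geom$dim[2], nz))
  if (params$postfilter_fwhm_mm > 0) {
    sigma <- params$postfilter_fwhm_mm / 2.3548
    vals <- gaussian_smooth(vals, sigma, geom$spacing)
    vals[vals < 0] <- 0
  }
  out <- vox_grid(vals, geom$spacing, geom$origin)
  attr(out, "n_zero_sensitivity") <- n_zero
  out
}

#' Poisson log-likelihood of a sinogram under an activity estimate
#'
#' Used to monitor MLEM convergence: `sum(y * log(ybar) - ybar)` over bins
#' with `ybar > 0`.
#'
#' @param sino [sinogram_set()] of counts.
#' @param activity [vox_grid()] estimate.
#' @param mu_for_ac [mu_map()] or `NULL`, as used in reconstruction.
#' @return scalar log-likelihood (up to the `y!` constant).
#' @export
poisson_loglik <- function(sino, activity, mu_for_ac = NULL) {
  geom <- sino$geometry
  sm <- system_matrix(geom)
  nz <- dim(sino$prompts)[3]
  F <- if (is.null(mu_for_ac)) 1
       else matrix(attenuation_factors(mu_for_ac, geom), ncol = nz)
  ybar <- F * as.matrix(sm$A %*% matrix(activity$values, ncol = nz))
  if (length(sino$background) == 1L) ybar <- ybar + sino$background
  else ybar <- ybar + matrix(sino$background, ncol = nz)
  y <- matrix(sino$prompts, ncol = nz)
  ok <- ybar > 0
  if (any(y[!ok] > 0)) return(-Inf)
  sum(y[ok] * log(ybar[ok]) - ybar[ok])
}

#' Write / read a sinogram as NIfTI with a JSON geometry sidecar
#'
#' @param sino [sinogram_set()].
#' @param path output `.nii/.nii.gz` path; the sidecar is `<path>.json`.
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` a
#'   [sinogram_set()] (without attenuation factors, which are recomputed from
#'   a mu-map when needed).
#' @export
write_sinogram <- function(sino, path) {
  g <- vox_grid(sino$prompts, c(sino$geometry$bin_spacing_mm,
                                180 / sino$geometry$n_angles,
                                sino$geometry$spacing[3]))
  write_volume(g, path)
  side <- list(n_angles = sino$geometry$n_angles,
               n_bins = sino$geometry$n_bins,
               bin_spacing_mm = sino$geometry$bin_spacing_mm,
               step_factor = sino$geometry$step_factor,
               image_dim = sino$geometry$dim,
               image_spacing = sino$geometry$spacing,
               image_origin = sino$geometry$origin,
               background = sino$background)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- read_volume(path)
  geom <- proj_geom(vox_grid(array(0, side$image_dim), side$image_spacing,
                             side$image_origin),
                    n_angles = side$n_angles, n_bins = side$n_bins,
                    bin_spacing_mm = side$bin_spacing_mm,
                    step_factor = side$step_factor)
  sinogram_set(img$values, array(1, dim(img$values)),
               side$background, geom)
}
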