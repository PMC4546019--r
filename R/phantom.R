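# Seeded synthetic head/neck phantom generator. The phantom provides the
# ground truth the study design needs but cannot ship: a body envelope with
# internal air cavities (oral cavity, sinuses), a true mu-map, a smooth
# activity map with reference ROIs, a Dixon-water-like anatomical image, and
# injectable dental-artifact voids of the two topological classes.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

ellipsoid_mask <- function(axes, center, semi) {
  ex <- ((axes[[1]] - center[1]) / semi[1])^2
  ey <- ((axes[[2]] - center[2]) / semi[2])^2
  ez <- ((axes[[3]] - center[3]) / semi[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) <= 1
}

cylinder_z_mask <- function(axes, center_xy, radius, z_range) {
  ex <- (axes[[1]] - center_xy[1])^2
  ey <- (axes[[2]] - center_xy[2])^2
  inplane <- outer(ex, ey, `+`) <= radius^2
  zin <- axes[[3]] >= z_range[1] & axes[[3]] <= z_range[2]
  outer(inplane, zin, `&`)
}

#' Specification of a synthetic head/neck phantom
#'
#' Holds the grid geometry, the anatomical primitives (head ellipsoid, neck
#' cylinder, oral cavity, sinuses), the reference-ROI placements, per-tissue
#' activity levels (arbitrary units), the fat attenuation value, the
#' anatomical jitter used for population/atlas building, and the seed.
#' All positions are world mm; the default grid is 96 x 96 x 64 voxels at
#' 2.6 x 2.6 x 3.1 mm, centred on the origin.
#'
#' @param geometry [vox_grid()] giving the grid (values ignored).
#' @param head_center,head_semi head ellipsoid centre and semi-axes (mm).
#' @param neck_radius,neck_center_xy,neck_z neck cylinder parameters (mm).
#' @param oral_center,oral_semi oral cavity air ellipsoid (mm).
#' @param sinus_centers list of sphere centres (mm); `sinus_radius` mm.
#' @param rois named list of `list(center=, semi=)` ellipsoids for the
#'   reference ROIs `tongue`, `lower_tongue`, `masticatory_left`,
#'   `masticatory_right`, `cerebellum`.
#' @param activity named activity levels (arbitrary units) per tissue class.
#' @param mu_fat fat attenuation in cm^-1 (< 0.1).
#' @param fat_fraction thickness fraction of the scalp fat shell (0 disables).
#' @param dental_margin_mm radius of the dental template band around the oral
#'   cavity; artifacts are generated inside it and the atlas mask targets it.
#' @param jitter_sd_mm anatomical jitter std (mm) used by [make_population()].
#' @param activity_noise_sd relative std of the smooth seeded activity texture.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = vox_grid(array(0, c(96L, 96L, 64L)),
                                             spacing = c(2.6, 2.6, 3.1)),
                         head_center = c(0, 5, 20), head_semi = c(75, 92, 70),
                         neck_radius = 55, neck_center_xy = c(0, 5),
                         neck_z = c(-99, -20),
                         oral_center = c(0, -42, -18), oral_semi = c(20, 12, 9),
                         sinus_centers = list(c(-18, -35, 15), c(18, -35, 15)),
                         sinus_radius = 8,
                         rois = list(
                           tongue = list(center = c(0, -27, -18), semi = c(15, 11, 8)),
                           lower_tongue = list(center = c(0, -30, -36), semi = c(12, 9, 7)),
                           masticatory_left = list(center = c(-38, -25, -6), semi = c(10, 8, 12)),
                           masticatory_right = list(center = c(38, -25, -6), semi = c(10, 8, 12)),
                           cerebellum = list(center = c(0, 38, 38), semi = c(28, 18, 14))
                         ),
                         activity = c(soft = 1.0, fat = 0.5, brain = 4.0,
                                      tongue = 1.5, masticatory = 0.8),
                         mu_fat = 0.086, fat_fraction = 0.05,
                         dental_margin_mm = 14,
                         jitter_sd_mm = 2.5,
                         activity_noise_sd = 0.05,
                         seed = 1L) {
  spec <- list(geometry = geometry, head_center = head_center,
               head_semi = head_semi, neck_radius = neck_radius,
               neck_center_xy = neck_center_xy, neck_z = neck_z,
               oral_center = oral_center, oral_semi = oral_semi,
               sinus_centers = sinus_centers, sinus_radius = sinus_radius,
               rois = rois, activity = activity, mu_fat = mu_fat,
               fat_fraction = fat_fraction,
               dental_margin_mm = dental_margin_mm,
               jitter_sd_mm = jitter_sd_mm,
               activity_noise_sd = activity_noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Apply seeded anatomical jitter: a global translation plus small
# per-structure centre/shape perturbations. Returns a jittered spec.
jitter_spec <- function(spec, sd_mm, seed) {
  if (sd_mm <= 0) return(spec)
  with_seed(seed, {
    shift <- rnorm(3, 0, sd_mm)
    spec$head_center <- spec$head_center + shift
    spec$neck_center_xy <- spec$neck_center_xy + shift[1:2]
    spec$oral_center <- spec$oral_center + shift + rnorm(3, 0, sd_mm / 2)
    spec$oral_semi <- pmax(3, spec$oral_semi * exp(rnorm(3, 0, 0.04)))
    spec$sinus_centers <- lapply(spec$sinus_centers,
                                 function(p) p + shift + rnorm(3, 0, sd_mm / 2))
    spec$rois <- lapply(spec$rois, function(r) {
      r$center <- r$center + shift + rnorm(3, 0, sd_mm / 3)
      r
    })
    spec
  })
}

#' Generate a phantom (without artifact)
#'
#' Rasterizes the anatomy of a [phantom_spec()] onto its grid and returns the
#' full ground truth: true and (initially identical) Dixon-style mu-maps, an
#' activity map, a Dixon-water-like image, the reference ROIs, the body mask,
#' and the dental template region. Deterministic for a fixed spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth` with fields `mu_truth`, `mu_dixon`,
#'   `activity`, `water`, `rois`, `void_truth` (empty), `body_mask`,
#'   `cavity_mask`, `sinus_mask`, `dental_region`, `artifacts` (empty list),
#'   and `spec`.
#' @export
make_phantom <- function(spec) {
  g <- spec$geometry
  axes <- grid_axes(g)
  d <- dim(g$values)
  sp <- g$spacing

  head <- ellipsoid_mask(axes, spec$head_center, spec$head_semi)
  neck <- cylinder_z_mask(axes, spec$neck_center_xy, spec$neck_radius,
                          spec$neck_z)
  body <- head | neck
  if (!any(body)) stop("spec error: body empty on grid", call. = FALSE)

  cavity <- ellipsoid_mask(axes, spec$oral_center, spec$oral_semi)
  if (!all(body[cavity])) stop("spec error: oral cavity outside body", call. = FALSE)
  sinus <- array(FALSE, d)
  for (p in spec$sinus_centers)
    sinus <- sinus | ellipsoid_mask(axes, p, rep(spec$sinus_radius, 3))
  if (!all(body[sinus])) stop("spec error: sinus outside body", call. = FALSE)

  air <- cavity | sinus
  tissue <- body & !air

  # scalp fat shell on the upper posterior head, away from the dental region
  fat <- array(FALSE, d)
  if (spec$fat_fraction > 0) {
    shell_mm <- spec$fat_fraction * min(spec$head_semi)
    inner_head <- ellipsoid_mask(axes, spec$head_center,
                                 spec$head_semi - shell_mm)
    zmask <- axes[[3]] > spec$head_center[3] + 15
    fat <- head & !inner_head &
      outer(array(TRUE, d[1:2]), zmask, `&`) & tissue
  }

  mu <- array(0, d)
  mu[tissue] <- MU_SOFT_TISSUE
  mu[fat] <- spec$mu_fat

  # ROI masks; masticatory_muscles is the union of left and right
  roi_masks <- lapply(spec$rois, function(r)
    ellipsoid_mask(axes, r$center, r$semi))
  for (nm in names(roi_masks)) {
    if (!all(body[roi_masks[[nm]]]))
      stop(sprintf("spec error: ROI '%s' outside body", nm), call. = FALSE)
  }
  brain <- ellipsoid_mask(axes, spec$head_center + c(0, 3, 25),
                          spec$head_semi * c(0.72, 0.72, 0.55))
  brain <- brain & tissue

  act <- array(0, d)
  act[tissue] <- spec$activity[["soft"]]
  act[fat] <- spec$activity[["fat"]]
  act[brain] <- spec$activity[["brain"]]
  act[roi_masks$tongue & tissue] <- spec$activity[["tongue"]]
  act[(roi_masks$masticatory_left | roi_masks$masticatory_right) & tissue] <-
    spec$activity[["masticatory"]]

  water <- array(0, d)
  water[tissue] <- 100
  water[fat] <- 60

  # seeded smooth texture for activity and water
  with_seed(spec$seed, {
    noise_a <- gaussian_smooth(array(rnorm(prod(d)), d), 6, sp)
    noise_w <- gaussian_smooth(array(rnorm(prod(d)), d), 6, sp)
  })
  if (spec$activity_noise_sd > 0) {
    na_sd <- stats::sd(noise_a)
    act <- act * (1 + spec$activity_noise_sd * noise_a / na_sd)
    water <- pmax(water * (1 + 0.08 * noise_w / stats::sd(noise_w)), 0)
  }
  act <- pmax(act, 0)
  act[!tissue] <- 0
  act[tissue] <- pmax(act[tissue], 0.05)  # activity > 0 in all tissue
  water[!tissue] <- 0

  dental <- dilate_mm(cavity, sp, spec$dental_margin_mm) & body

  rois <- roi_set(
    c(roi_masks[c("tongue", "lower_tongue", "cerebellum")],
      list(masticatory_muscles = roi_masks$masticatory_left |
             roi_masks$masticatory_right)),
    g)

  ph <- list(
    mu_truth = mu_map(vox_grid(mu, sp, g$origin), body_mask = body,
                      provenance = "truth"),
    mu_dixon = mu_map(vox_grid(mu, sp, g$origin), body_mask = NULL,
                      provenance = "dixon"),
    activity = vox_grid(act, sp, g$origin),
    water = vox_grid(water, sp, g$origin),
    rois = rois,
    void_truth = array(FALSE, d),
    body_mask = body,
    cavity_mask = cavity,
    sinus_mask = sinus,
    dental_region = dental,
    artifacts = list(),
    spec = spec
  )
  class(ph) <- "phantom_truth"
  ph
}

#' @export
#' @method print phantom_truth
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> body %.0f mL, cavity %.1f mL, void %.1f mL (%d artifact%s)\n",
              sum(x$body_mask) * voxel_volume_ml(x$activity),
              sum(x$cavity_mask) * voxel_volume_ml(x$activity),
              sum(x$void_truth) * voxel_volume_ml(x$activity),
              length(x$artifacts), if (length(x$artifacts) == 1) "" else "s"))
  invisible(x)
}

#' Specification of a dental-artifact void
#'
#' @param class `"inner"` (void fully enclosed by the body) or `"outer"`
#'   (void breaching the body contour through a cheek channel to background
#'   air).
#' @param target_ml target realized void volume in mL (zeroed tissue); the
#'   generator realizes it within 15%.
#' @param seed RNG seed for the random ellipsoid union.
#' @param centroid optional world-mm centroid; defaults to a seeded point on
#'   the anterior oral-cavity wall (the teeth region).
#' @param channel_radius_mm breach channel radius for `"outer"` voids.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(class = c("inner", "outer"), target_ml, seed = 1L,
                          centroid = NULL, channel_radius_mm = 6) {
  class <- match.arg(class)
  if (!is.finite(target_ml) || target_ml < 0)
    stop("spec error: target_ml must be >= 0", call. = FALSE)
  structure(list(class = class, target_ml = target_ml, seed = as.integer(seed),
                 centroid = centroid, channel_radius_mm = channel_radius_mm),
            class = "artifact_spec")
}

#' Inject a dental-artifact void into a phantom
#'
#' Zeroes `mu_dixon` (and the water image, emulating the MR signal void) on a
#' seeded union of random ellipsoids near the teeth region. `"inner"` voids
#' are constrained so that even their one-voxel dilation stays inside the
#' body; `"outer"` voids additionally carve a cylindrical channel through the
#' anterior cheek so the void is face-connected to background air. The
#' realized void volume (zeroed tissue) is within 15% of `target_ml`.
#'
#' @param ph a [make_phantom()] result.
#' @param art an [artifact_spec()].
#' @return the modified `phantom_truth`.
#' @export
inject_artifact <- function(ph, art) {
  stopifnot(inherits(ph, "phantom_truth"), inherits(art, "artifact_spec"))
  if (art$target_ml == 0) return(ph)
  g <- ph$activity
  sp <- g$spacing
  axes <- grid_axes(g)
  d <- dim(g$values)
  vml <- voxel_volume_ml(g)
  tissue <- ph$mu_truth$grid$values > 0
  solid <- fill_holes(ph$body_mask)

  # placement region: near the dental arch for inner; anywhere in the
  # anterior half of the head for large outer voids
  # margin so that even a one-voxel (26-neighbour) dilation of the void
  # stays inside the body: erode the solid body by an L1 radius of 3
  enclosed_ok <- erode6(solid, 3L)
  if (art$class == "inner") {
    allowed <- ph$dental_region & enclosed_ok
  } else {
    zband <- abs(axes[[3]] - ph$spec$oral_center[3]) <= 55
    yfront <- axes[[2]] <= ph$spec$head_center[2] + 25
    allowed <- solid &
      outer(outer(rep(TRUE, d[1]), yfront, `&`), zband, `&`)
  }
  cap_ml <- sum(allowed & tissue) * vml
  if (art$target_ml > cap_ml)
    stop(sprintf("spec error: target %.1f mL exceeds region capacity %.1f mL",
                 art$target_ml, cap_ml), call. = FALSE)

  centroid <- art$centroid
  void <- array(FALSE, d)
  with_seed(art$seed, {
    if (is.null(centroid)) {
      # a point on the anterior oral-cavity wall
      th <- runif(1, -0.9, 0.9)
      centroid <- ph$spec$oral_center +
        c(sin(th) * ph$spec$oral_semi[1] * 0.8,
          -cos(th) * ph$spec$oral_semi[2] * 0.9,
          runif(1, -0.4, 0.4) * ph$spec$oral_semi[3])
    }
    realized <- function() sum(void & tissue) * vml
    # primary blob sized for the target, then incremental top-up blobs
    r0 <- (3 * art$target_ml * 1000 / (4 * pi))^(1 / 3)
    semi <- r0 * exp(rnorm(3, 0, 0.15)); semi <- semi / prod(semi)^(1/3) * r0
    void <- ellipsoid_mask(axes, centroid, pmax(semi, 1.5 * sp)) & allowed
    tries <- 0L
    while (realized() < 0.9 * art$target_ml && tries < 400L) {
      tries <- tries + 1L
      # grow from a random point on the current void/centroid neighbourhood
      anchor <- if (any(void) && runif(1) < 0.8) {
        i <- sample(which(void), 1L)
        c(axes[[1]][(i - 1) %% d[1] + 1],
          axes[[2]][((i - 1) %/% d[1]) %% d[2] + 1],
          axes[[3]][(i - 1) %/% (d[1] * d[2]) + 1])
      } else centroid
      miss <- max(art$target_ml - realized(), 0.05 * art$target_ml)
      rb <- (3 * min(miss, 0.15 * art$target_ml) * 1000 / (4 * pi))^(1 / 3)
      blob <- ellipsoid_mask(axes, anchor + rnorm(3, 0, rb),
                             pmax(rb * exp(rnorm(3, 0, 0.2)), 1.2 * sp)) &
        allowed
      # a susceptibility void is one connected region: only grow by blobs
      # that touch the existing void
      if (any(void) && !any(blob & void)) next
      void <- void | blob
    }
    if (realized() < 0.85 * art$target_ml)
      stop("spec error: could not realize target volume in dental region",
           call. = FALSE)
  })

  if (art$class == "outer") {
    # breach channel: cylinder along -y from the centroid through the cheek
    ex <- (axes[[1]] - centroid[1])^2
    ez <- (axes[[3]] - centroid[3])^2
    xz <- outer(ex, ez, `+`) <= art$channel_radius_mm^2   # nx x nz
    ysel <- axes[[2]] <= centroid[2]
    channel <- aperm(outer(xz, ysel, `&`), c(1, 3, 2))    # nx x ny x nz
    void <- void | (channel & solid)
  }

  new_void <- void & tissue
  mu_d <- ph$mu_dixon$grid$values
  mu_d[void] <- 0
  ph$mu_dixon <- mu_map(vox_grid(mu_d, sp, g$origin), body_mask = NULL,
                        provenance = "dixon")
  w <- ph$water$values
  w[void] <- 0
  ph$water <- vox_grid(w, sp, g$origin)
  ph$void_truth <- ph$void_truth | new_void
  ph$artifacts <- c(ph$artifacts, list(list(
    spec = art,
    centroid = centroid,
    realized_ml = sum(new_void) * vml
  )))
  ph
}

#' Generate a population of artifact-free phantoms
#'
#' Used for atlas construction: `n` phantoms with independent anatomical
#' jitter, deterministic per `(seed, index)`.
#'
#' @param spec a [phantom_spec()]; its `jitter_sd_mm` controls the anatomy
#'   variation.
#' @param n number of subjects (>= 1).
#' @param seed population seed.
#' @return list of `phantom_truth` objects.
#' @export
make_population <- function(spec, n, seed = spec$seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("argument error: n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    si <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    sp_i <- jitter_spec(spec, spec$jitter_sd_mm, si)
    sp_i$seed <- si
    make_phantom(sp_i)
  })
}
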