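# Atlas construction, affine registration of the patient's Dixon-water-like
# image, and the template-mask fill with the 80%/10% completion/reversal
# policy (workflow step 2).

#' Fill policy for template-masked voids
#'
#' Components whose mask-overlap fraction is strictly above
#' `complete_threshold` are filled completely; strictly below
#' `reverse_threshold` the partial fill is considered an error and reversed;
#' in between the partial fill is kept. Fractions exactly at a threshold fall
#' in the kept-partial band.
#'
#' @param fill_value attenuation assigned to filled voxels (cm^-1).
#' @param complete_threshold completion threshold, default 0.80.
#' @param reverse_threshold reversal threshold, default 0.10.
#' @return object of class `fill_policy`.
#' @export
fill_policy <- function(fill_value = MU_SOFT_TISSUE,
                        complete_threshold = 0.80, reverse_threshold = 0.10) {
  if (!(reverse_threshold >= 0 && reverse_threshold < complete_threshold &&
        complete_threshold <= 1))
    stop("argument error: need 0 <= reverse < complete <= 1", call. = FALSE)
  structure(list(fill_value = fill_value,
                 complete_threshold = complete_threshold,
                 reverse_threshold = reverse_threshold),
            class = "fill_policy")
}

#' Build an atlas from artifact-free water images
#'
#' The atlas is the voxelwise mean water image of the population plus two
#' derived masks: the oral-cavity template (the dental region in which signal
#' voids are assumed metallic in origin: the population-consensus oral-cavity
#' air core dilated by the dental margin, restricted to the consensus body)
#' and the anatomical-air union (air in at least `q_any` of subjects, dilated
#' one voxel) used to recognize normal air cavities.
#'
#' @param waters list of geometry-compatible [vox_grid()] water images from
#'   artifact-free subjects.
#' @param water_air_threshold water intensity below which a voxel counts as
#'   air.
#' @param q consensus quantile for the oral-cavity core (fraction of subjects
#'   in which a voxel must be air), default 0.9.
#' @param q_any quantile for the anatomical-air union, default 0.2.
#' @param dental_margin_mm dilation radius of the template band, default 14.
#' @return object of class `mu_atlas` with `mean_water`, `oral_cavity_mask`,
#'   `air_union`, `consensus_air`, `n_subjects`.
#' @export
build_atlas <- function(waters, water_air_threshold = 20, q = 0.9,
                        q_any = 0.2, dental_margin_mm = 14) {
  if (!length(waters)) stop("argument error: empty water list", call. = FALSE)
  g0 <- waters[[1]]
  acc <- array(0, dim(g0$values))
  airfrac <- array(0, dim(g0$values))
  for (w in waters) {
    stop_if_incompatible(g0, w, "atlas water images")
    acc <- acc + w$values
    airfrac <- airfrac + (w$values < water_air_threshold)
  }
  meanw <- acc / length(waters)
  airfrac <- airfrac / length(waters)

  # median-consensus body outline: using the strict q-consensus here can
  # thin the cheek wall below one voxel and topologically merge the oral
  # cavity with the background, defeating the hole filling
  body_cons <- airfrac <= 0.5
  inside <- fill_holes(label_components(body_cons, 26L) == 1L)
  consensus_air <- (airfrac >= q) & inside
  lab <- label_components(consensus_air, 26L)
  core <- lab == 1L                      # largest internal air cavity
  if (!any(core))
    stop("atlas error: no consensus oral-cavity air found", call. = FALSE)
  # one-voxel dilation compensates the erosion of the q-consensus before the
  # dental margin is applied
  core <- dilate6(core, 1L)
  mask <- dilate_mm(core, g0$spacing, dental_margin_mm) & inside
  air_union <- dilate6((airfrac >= q_any), 1L)
  # voxel-level protection of anatomical air during filling: internal
  # median air (oral cavity, sinuses) dilated one voxel to absorb the
  # residual registration error. The contour fill (step 1) trusts the
  # patient-specific contour for the body outline, so only internal air is
  # protected there; the template fill (step 2) additionally protects the
  # background median air.
  median_air <- airfrac >= 0.5
  protect_contour <- dilate6(median_air & inside, 1L)
  protect_mask <- dilate6(median_air & inside, 1L) | (median_air & !inside)

  structure(list(mean_water = vox_grid(meanw, g0$spacing, g0$origin),
                 oral_cavity_mask = mask, air_union = air_union,
                 protect_contour = protect_contour,
                 protect_mask = protect_mask,
                 consensus_air = consensus_air, inside = inside,
                 n_subjects = length(waters),
                 params = list(water_air_threshold = water_air_threshold,
                               q = q, q_any = q_any,
                               dental_margin_mm = dental_margin_mm)),
            class = "mu_atlas")
}

#' @export
#' @method print mu_atlas
print.mu_atlas <- function(x, ...) {
  cat(sprintf("<mu_atlas> %d subjects, template %.1f mL, air union %.1f mL\n",
              x$n_subjects,
              sum(x$oral_cavity_mask) * voxel_volume_ml(x$mean_water),
              sum(x$air_union) * voxel_volume_ml(x$mean_water)))
  invisible(x)
}

# 12-dof affine from parameter vector: translation (mm), rotation (rad),
# log-scale, shear. Maps world -> world about `center`.
affine_from_params <- function(par, center = c(0, 0, 0)) {
  t <- par[1:3]; r <- par[4:6]; ls <- par[7:9]; sh <- par[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(exp(ls))
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center - A %*% center + t
  M
}

# Sample a grid's values at world points (n x 3), trilinear; outside -> 0.
sample_world <- function(grid, pts, method = "trilinear") {
  ix <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  iy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  iz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  interp3_points(grid$values, ix, iy, iz, method)
}

world_coords <- function(grid) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

down_grid <- function(grid, f) {
  vox_grid(downsample_mean(grid$values, f), grid$spacing * f,
           grid$origin + (f - 1) * grid$spacing / 2)
}

#' Register a patient water image to the atlas
#'
#' Estimates the 12-dof affine transform mapping patient world coordinates to
#' atlas world coordinates by minimizing the mean-squared difference of
#' normalized, smoothed images over a multi-resolution pyramid. Voxels that
#' are sub-threshold (air or signal void) in the patient image are excluded
#' from the metric, which keeps large artifact voids from dragging the fit.
#' Deterministic (identity initialization).
#'
#' @param patient_water [vox_grid()].
#' @param atlas a [build_atlas()] result.
#' @param water_air_threshold exclusion threshold on the patient image.
#' @param smooth_mm Gaussian pre-smoothing (mm).
#' @return object of class `atlas_transform`: `M` (4x4 patient-to-atlas
#'   world affine), `par`, `metric`, `converged`.
#' @export
register_to_atlas <- function(patient_water, atlas, water_air_threshold = 20,
                              smooth_mm = 4) {
  stop_if_incompatible(patient_water, atlas$mean_water,
                       "patient and atlas water images")
  sm_p <- vox_grid(gaussian_smooth(patient_water$values, smooth_mm,
                                   patient_water$spacing),
                   patient_water$spacing, patient_water$origin)
  sm_a <- vox_grid(gaussian_smooth(atlas$mean_water$values, smooth_mm,
                                   atlas$mean_water$spacing),
                   atlas$mean_water$spacing, atlas$mean_water$origin)
  norm01 <- function(g) new_like(g, robust_normalize(g$values))
  sm_p <- norm01(sm_p); sm_a <- norm01(sm_a)
  thr <- water_air_threshold / max(patient_water$values, 1e-9)

  cost_at <- function(level) {
    p <- down_grid(sm_p, level); a <- down_grid(sm_a, level)
    excl <- down_grid(vox_grid((patient_water$values >
                                  water_air_threshold) * 1,
                               patient_water$spacing, patient_water$origin),
                      level)
    keep <- which(excl$values > 0.5)
    if (length(keep) > 8000L)  # deterministic stride subsample
      keep <- keep[round(seq(1L, length(keep), length.out = 8000L))]
    pts <- world_coords(p)[keep, , drop = FALSE]
    pv <- p$values[keep]
    function(par) {
      M <- affine_from_params(par)
      tp <- pts %*% t(M[1:3, 1:3]) +
        matrix(M[1:3, 4], nrow(pts), 3, byrow = TRUE)
      av <- sample_world(a, tp)
      mean((pv - av)^2)
    }
  }

  par <- rep(0, 12)
  parscale <- c(rep(2, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))
  # coarse: translation only; finer: full affine
  f4 <- cost_at(4L)
  o1 <- stats::optim(par[1:3], function(p3) f4(c(p3, par[4:12])),
                     method = "BFGS",
                     control = list(maxit = 100, reltol = 1e-9,
                                    parscale = parscale[1:3]))
  par[1:3] <- o1$par
  f2 <- cost_at(2L)
  v0 <- f2(par)
  o2 <- stats::optim(par, f2, method = "BFGS",
                     control = list(maxit = 60, reltol = 1e-9,
                                    parscale = parscale))
  if (!is.finite(o2$value))
    stop("registration error: optimizer diverged", call. = FALSE)
  # reaching the iteration cap with an improved metric still counts as a
  # successful fit; `converged` flags genuine failures
  structure(list(M = affine_from_params(o2$par), par = o2$par,
                 metric = o2$value,
                 converged = o2$convergence == 0L || o2$value <= v0 + 1e-12),
            class = "atlas_transform")
}

#' @export
#' @method print atlas_transform
print.atlas_transform <- function(x, ...) {
  cat(sprintf("<atlas_transform> translation (%.2f, %.2f, %.2f) mm, metric %.3g\n",
              x$par[1], x$par[2], x$par[3], x$metric))
  invisible(x)
}

#' Identity atlas transform (registration fallback)
#' @return an `atlas_transform` with the identity affine.
#' @export
identity_transform <- function() {
  structure(list(M = diag(4), par = rep(0, 12), metric = NA_real_,
                 converged = TRUE), class = "atlas_transform")
}

# Pull an atlas-space mask into patient space: patient voxel x takes the
# nearest-neighbour mask value at the atlas point M x.
warp_mask_to_patient <- function(mask_atlas, atlas_grid, patient_grid, M) {
  pts <- world_coords(patient_grid) %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], prod(dim(patient_grid$values)), 3, byrow = TRUE)
  vals <- sample_world(vox_grid(mask_atlas * 1, atlas_grid$spacing,
                                atlas_grid$origin),
                       pts, method = "nearest")
  array(vals > 0.5, dim(patient_grid$values))
}

#' Fill template-masked voids and apply the completion/reversal policy
#'
#' For each detected void component the overlap fraction with the warped
#' oral-cavity template is computed. Components recognized as normal
#' anatomical air (overlap with the atlas anatomical-air union above
#' `anatomical_threshold`) are left untouched. Otherwise: fraction strictly
#' above the completion threshold fills the entire component with soft
#' tissue; strictly below the reversal threshold reverts the component;
#' in between exactly the template-overlapping voxels are filled.
#'
#' @param mu [mu_map()] the (possibly contour-closed) attenuation map.
#' @param voids [detect_voids()] result on `mu`.
#' @param atlas [build_atlas()] result (or `NULL` when `mask_patient` is
#'   given directly).
#' @param transform [register_to_atlas()] result (patient-to-atlas affine).
#' @param policy a [fill_policy()].
#' @param mask_patient optional logical array: the template already in
#'   patient space (overrides atlas + transform).
#' @param anatomical_threshold fraction of a component inside the atlas
#'   anatomical-air union above which it is classified as normal anatomy and
#'   skipped (`Inf` or a `NULL` atlas disables the check). Default 0.95.
#' @return list with `mu` (the filled [mu_map()]), `report` (data.frame per
#'   component: `id`, `n_voxels`, `fraction`, `action`, `voxels_changed`),
#'   and `changed_mask`.
#' @export
fill_masked_voids <- function(mu, voids, atlas = NULL, transform = NULL,
                              policy = fill_policy(), mask_patient = NULL,
                              anatomical_threshold = 0.95) {
  g <- mu$grid
  if (is.null(mask_patient)) {
    if (is.null(atlas) || is.null(transform))
      stop("argument error: need atlas+transform or mask_patient", call. = FALSE)
    mask_patient <- warp_mask_to_patient(atlas$oral_cavity_mask,
                                         atlas$mean_water, g, transform$M)
  }
  air_union_patient <- if (!is.null(atlas) &&
                           is.finite(anatomical_threshold)) {
    warp_mask_to_patient(atlas$air_union, atlas$mean_water, g,
                         if (is.null(transform)) diag(4) else transform$M)
  } else NULL
  protect_patient <- if (!is.null(atlas))
    warp_mask_to_patient(atlas$protect_mask, atlas$mean_water, g,
                         if (is.null(transform)) diag(4) else transform$M)
  else NULL

  vals <- g$values
  changed <- array(FALSE, dim(vals))
  rows <- list()
  for (i in seq_len(nrow(voids$components))) {
    id <- voids$components$id[i]
    comp <- component_mask(voids, id)
    n <- sum(comp)
    overlap <- comp & mask_patient
    frac <- sum(overlap) / n
    action <- if (!is.null(air_union_patient) &&
                  sum(comp & air_union_patient) / n > anatomical_threshold) {
      "anatomical"
    } else if (frac > policy$complete_threshold) {
      "completed"
    } else if (frac < policy$reverse_threshold) {
      "reversed"
    } else "kept_partial"
    fillmask <- switch(action,
                       completed = comp,
                       kept_partial = overlap,
                       NULL)
    nch <- 0L
    if (!is.null(fillmask)) {
      if (!is.null(protect_patient)) fillmask <- fillmask & !protect_patient
      sel <- fillmask & vals < policy$fill_value
      vals[sel] <- policy$fill_value
      changed <- changed | sel
      nch <- sum(sel)
    }
    rows[[i]] <- data.frame(id = id, n_voxels = n, fraction = frac,
                            action = action, voxels_changed = nch)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), n_voxels = integer(0), fraction = numeric(0),
               action = character(0), voxels_changed = integer(0))
  list(mu = mu_map(vox_grid(vals, g$spacing, g$origin),
                   body_mask = mu$body_mask, provenance = mu$provenance),
       report = report, changed_mask = changed)
}

#' Full inpainting pipeline for one attenuation map
#'
#' Runs the two-step correction: (1) for outer-class voids, delineate and
#' close the body contour with the switched Chan-Vese level set driven by
#' NAC-PET and fill the enclosed breached voids with soft tissue; (2) detect
#' the remaining voids, align the patient water image to the atlas, fill
#' template-overlapping voids and apply the completion/reversal policy.
#' Artifact-free inputs pass through unchanged.
#'
#' @param mu_dixon [mu_map()] the uncorrected map.
#' @param nac_pet [vox_grid()] non-attenuation-corrected PET.
#' @param patient_water [vox_grid()] Dixon-water-like image.
#' @param atlas [build_atlas()] result.
#' @param policy a [fill_policy()].
#' @param ls_params [levelset_params()] or `"auto"`.
#' @param air_threshold air threshold (cm^-1).
#' @return object of class `inpaint_result`: `mu_inpainted` (provenance
#'   `"inpainted"`), `changed_mask` (the fully inpainted area),
#'   `fill_report`, `contour` (or `NULL`), `voids_initial`, `voids_residual`,
#'   `transform`, `stages` (log of per-stage outcomes).
#' @export
inpaint <- function(mu_dixon, nac_pet, patient_water, atlas,
                    policy = fill_policy(), ls_params = "auto",
                    air_threshold = 0.005) {
  stages <- list()
  run_stage <- function(name, expr) {
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline error in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- "ok"
    out
  }

  voids0 <- run_stage("detect", detect_voids(mu_dixon, air_threshold))
  evidence <- run_stage("outer_evidence",
                        outer_void_evidence(nac_pet, mu_dixon, air_threshold))
  transform <- run_stage("register", register_to_atlas(patient_water, atlas))
  # air in the median atlas anatomy (oral cavity, sinuses and free
  # background) must stay air in every fill action
  protect <- warp_mask_to_patient(atlas$protect_contour, atlas$mean_water,
                                  mu_dixon$grid, transform$M)
  contour <- NULL
  mu1 <- mu_dixon
  step1_filled <- array(FALSE, dim(mu_dixon$grid$values))
  # a true breach always leaves tracer signal outside the mu-map body, so
  # the PET evidence is the trigger (a pre-closure component can classify
  # "outer" from incidental surface air without any real breach)
  if (attr(evidence, "volume_ml") >= 2) {
    if (identical(ls_params, "auto"))
      ls_params <- run_stage("auto_parameters",
                             auto_parameters(nac_pet, mu_dixon, air_threshold))
    contour <- run_stage("contour",
                         evolve_contour(mu_dixon, nac_pet, ls_params,
                                        voids = voids0,
                                        air_threshold = air_threshold))
    mu1 <- run_stage("close_and_fill",
                     close_and_fill(mu_dixon, contour, protect = protect))
    step1_filled <- attr(mu1, "filled_mask")
  }

  voids1 <- run_stage("detect_residual", detect_voids(mu1, air_threshold))
  fill <- NULL
  step2_changed <- array(FALSE, dim(mu_dixon$grid$values))
  mu2 <- mu1
  if (nrow(voids1$components)) {
    fill <- run_stage("fill", fill_masked_voids(mu1, voids1, atlas, transform,
                                                policy))
    mu2 <- fill$mu
    step2_changed <- fill$changed_mask
  }

  # the template fill can turn residual surface nooks into pinholes;
  # re-seal after step 2 so the closed boundary stays closed
  if (!is.null(contour)) {
    cand <- (voids0$outer_air | voids0$border_air) &
      mu_dixon$grid$values < MU_SOFT_TISSUE
    sealed <- seal_surface_leaks(mu2$grid$values, cand,
                                 contour$contour_mask, protect)
    if (any(sealed$filled)) {
      mu2 <- mu_map(vox_grid(sealed$vals, mu2$grid$spacing, mu2$grid$origin),
                    body_mask = mu2$body_mask, provenance = mu2$provenance)
      step2_changed <- step2_changed | sealed$filled
    }
  }
  changed <- step1_filled | step2_changed
  mu_out <- mu_map(mu2$grid, body_mask = mu_dixon$body_mask,
                   provenance = "inpainted")
  structure(list(mu_inpainted = mu_out, changed_mask = changed,
                 fill_report = if (is.null(fill))
                   fill_masked_voids(mu1, voids1, policy = policy,
                                     mask_patient = array(FALSE, dim(changed)),
                                     anatomical_threshold = Inf)$report
                 else fill$report,
                 contour = contour, voids_initial = voids0,
                 voids_residual = voids1, transform = transform,
                 stages = stages),
            class = "inpaint_result")
}

#' @export
#' @method print inpaint_result
print.inpaint_result <- function(x, ...) {
  cat(sprintf("<inpaint_result> %d voxels inpainted (%.1f mL); %d initial component(s)\n",
              sum(x$changed_mask),
              sum(x$changed_mask) * voxel_volume_ml(x$mu_inpainted$grid),
              nrow(x$voids_initial$components)))
  if (nrow(x$fill_report)) print(x$fill_report)
  invisible(x)
}
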