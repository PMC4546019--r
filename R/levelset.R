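# Two-channel Chan-Vese level-set delineation of the anatomical outer
# contour. In areas without signal voids the data term follows the mu-map;
# inside a dilation of outer-class voids a switch field hands the data term
# to the NAC-PET image, whose apparent body edge survives the MR signal void.
# Closing the contour there restores the anatomical boundary breached by the
# artifact.

robust_normalize <- function(a, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(a, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim(a)))
  pmin(pmax((a - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Level-set parameters
#'
#' @param nu curvature (length penalty) weight, >= 0, on the normalized
#'   channels.
#' @param lambda_mr,lambda_pet data weights of the mu-map and NAC-PET
#'   channels (not both 0).
#' @param max_iter maximum iterations.
#' @param reinit_interval iterations between signed-distance
#'   reinitializations.
#' @param tol convergence tolerance: fraction of voxels changing sign per
#'   iteration, must hold for 5 consecutive iterations. In (0, 1).
#' @param dt explicit time step (stability-normalized update).
#' @param min_iter warm-up iterations before the convergence test engages
#'   (the contour may need to travel far across large breached voids before
#'   the sign-change rate picks up).
#' @param switch_dilate_mm dilation radius (mm) of the outer-void region that
#'   defines the PET-dominant switch field.
#' @return object of class `levelset_params`.
#' @export
levelset_params <- function(nu = 0.2, lambda_mr = 1, lambda_pet = 1,
                            max_iter = 300L, reinit_interval = 50L,
                            tol = 2e-5, dt = 0.8, min_iter = 30L,
                            switch_dilate_mm = 8) {
  if (lambda_mr < 0 || lambda_pet < 0 || (lambda_mr == 0 && lambda_pet == 0))
    stop("argument error: lambda_mr, lambda_pet >= 0 and not both 0",
         call. = FALSE)
  if (tol <= 0 || tol >= 1) stop("argument error: tol in (0,1)", call. = FALSE)
  structure(list(nu = nu, lambda_mr = lambda_mr, lambda_pet = lambda_pet,
                 max_iter = as.integer(max_iter),
                 reinit_interval = as.integer(reinit_interval),
                 tol = tol, dt = dt, min_iter = as.integer(min_iter),
                 switch_dilate_mm = switch_dilate_mm),
            class = "levelset_params")
}

#' Automatic level-set parameterization from the PET signal
#'
#' Estimates the PET background statistics over voxels outside the mu-map
#' body envelope and sets the NAC-PET data weight from the contrast between
#' that background and the PET intensity just inside the envelope. Both
#' channels are percentile-normalized before use, so the parameterization is
#' invariant to global PET scaling. Weights are clamped to `[0.25, 8]`.
#'
#' @param nac_pet [vox_grid()] non-attenuation-corrected PET.
#' @param mu_dixon [mu_map()] the uncorrected attenuation map.
#' @param air_threshold air threshold (cm^-1) for the envelope.
#' @return a [levelset_params()].
#' @export
auto_parameters <- function(nac_pet, mu_dixon, air_threshold = 0.005) {
  stop_if_incompatible(as_grid(nac_pet), mu_dixon$grid, "NAC-PET and mu-map")
  env <- body_envelope(mu_dixon, air_threshold)
  outside <- !dilate6(env, 2L)
  if (!any(outside))
    stop("degenerate-input error: no voxels outside the body envelope",
         call. = FALSE)
  p <- robust_normalize(as_grid(nac_pet)$values)
  rim_in <- env & !erode6(env, 2L)
  m_out <- mean(p[outside])
  m_in <- mean(p[rim_in])
  contrast <- max(m_in - m_out, 0.05)
  # the PET residual contrast in void areas is intrinsically weaker than the
  # mu-map contrast elsewhere, so the PET weight scales inversely with it
  lambda_pet <- min(max(2 / contrast, 0.5), 10)
  levelset_params(lambda_pet = lambda_pet)
}

#' Evidence of boundary-breaching voids from the NAC-PET image
#'
#' Voxels outside the naive mu-map body envelope whose NAC-PET intensity is
#' well above the outside background level indicate body regions lost to a
#' signal void that breached the contour. The returned mask (and its volume)
#' decides whether the contour-closing step runs and where the level-set
#' switch field hands the data term to the PET channel.
#'
#' @param nac_pet [vox_grid()] non-attenuation-corrected PET.
#' @param mu [mu_map()] uncorrected attenuation map.
#' @param air_threshold air threshold (cm^-1).
#' @return logical array with attribute `"volume_ml"`.
#' @export
outer_void_evidence <- function(nac_pet, mu, air_threshold = 0.005) {
  g <- as_grid(nac_pet)
  env0 <- body_envelope(mu, air_threshold)
  p <- robust_normalize(g$values)
  far_out <- !dilate6(env0, 3L)
  m_out <- if (any(far_out)) mean(p[far_out]) else 0
  rim_in <- env0 & !erode6(env0, 2L)
  m_in <- if (any(rim_in)) mean(p[rim_in]) else 1
  thr <- m_out + 0.3 * max(m_in - m_out, 0.05)
  ev <- (p > thr) & !dilate6(env0, 1L)
  # discard isolated blur slivers
  lab <- label_components(ev, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * voxel_volume_ml(g) >= 0.25)
  ev <- if (length(keep)) array(lab %in% keep, dim(ev)) else
    array(FALSE, dim(ev))
  attr(ev, "volume_ml") <- sum(ev) * voxel_volume_ml(g)
  ev
}

# Surface-pit sealing: a contour that follows the blurred PET edge can miss
# single surface voxels of the void, leaving a pinhole connection to the
# background. Background-reachable air pits (>= 3 of 6 face neighbours
# tissue) within one voxel of the contour are closed.
seal_surface_leaks <- function(vals, cand, contour_mask, protect = NULL) {
  shell <- dilate6(contour_mask, 1L)
  if (!is.null(protect)) cand <- cand & !protect
  tissue <- vals >= 0.005
  reach <- flood_from_border(!tissue)
  nb <- shift_array(tissue, 1L) + shift_array(tissue, -1L) +
    shift_array(tissue, 0L, 1L) + shift_array(tissue, 0L, -1L) +
    shift_array(tissue, 0L, 0L, 1L) + shift_array(tissue, 0L, 0L, -1L)
  pit <- cand & !tissue & shell & reach & nb >= 3L
  vals[pit] <- MU_SOFT_TISSUE
  list(vals = vals, filled = pit)
}

signed_distance <- function(inside, spacing) {
  inside <- inside != 0
  distance_mm(inside, spacing) - distance_mm(!inside, spacing)
}

cv_curvature <- function(phi) {
  eps <- 1e-8
  gx <- (shift_array(phi, -1L) - shift_array(phi, 1L)) / 2
  gy <- (shift_array(phi, 0L, -1L) - shift_array(phi, 0L, 1L)) / 2
  gz <- (shift_array(phi, 0L, 0L, -1L) - shift_array(phi, 0L, 0L, 1L)) / 2
  mag <- sqrt(gx^2 + gy^2 + gz^2 + eps)
  nx <- gx / mag; ny <- gy / mag; nz <- gz / mag
  (shift_array(nx, -1L) - shift_array(nx, 1L)) / 2 +
    (shift_array(ny, 0L, -1L) - shift_array(ny, 0L, 1L)) / 2 +
    (shift_array(nz, 0L, 0L, -1L) - shift_array(nz, 0L, 0L, 1L)) / 2
}

cv_energy <- function(inside, img_mr, img_pet, w_mr, w_pet, nu) {
  e <- 0
  for (ch in list(list(img_mr, w_mr), list(img_pet, w_pet))) {
    img <- ch[[1]]; wgt <- ch[[2]]
    if (sum(wgt) == 0) next
    win <- wgt * inside; wout <- wgt * !inside
    c1 <- if (sum(win) > 0) sum(img * win) / sum(win) else 0
    c2 <- if (sum(wout) > 0) sum(img * wout) / sum(wout) else 0
    e <- e + sum(win * (img - c1)^2) + sum(wout * (img - c2)^2)
  }
  # length surrogate: count of sign-boundary faces
  b <- inside != shift_array(inside, 1L) | inside != shift_array(inside, 0L, 1L) |
    inside != shift_array(inside, 0L, 0L, 1L)
  e + nu * sum(b)
}

#' Evolve the body contour by the switched two-channel Chan-Vese energy
#'
#' Minimizes curvature + `lambda_mr (1-w)` two-region residual on the
#' normalized mu-map + `lambda_pet w` two-region residual on the normalized
#' NAC-PET, where the switch field `w` is 1 on a dilation of outer-class
#' voids and 0 elsewhere. The level-set function starts as the signed
#' distance to the naive mu-map body threshold and is reinitialized
#' periodically. Returns the contour at convergence or at `max_iter` with
#' `converged = FALSE` (with a warning).
#'
#' @param mu_dixon [mu_map()].
#' @param nac_pet [vox_grid()] NAC-PET image.
#' @param params [levelset_params()], e.g. from [auto_parameters()].
#' @param voids optional [detect_voids()] result on `mu_dixon`; used to build
#'   the switch field from outer-class components (computed if missing).
#' @param air_threshold air threshold (cm^-1).
#' @return object of class `contour_result`: `contour_mask` (single
#'   connected, hole-filled), `filled_mask` (void voxels enclosed by the
#'   contour that the closing will set to soft tissue), `iterations`,
#'   `converged`, `energy` trace.
#' @export
evolve_contour <- function(mu_dixon, nac_pet, params = levelset_params(),
                           voids = NULL, air_threshold = 0.005) {
  g <- mu_dixon$grid
  stop_if_incompatible(g, as_grid(nac_pet), "mu-map and NAC-PET")
  if (is.null(voids)) voids <- detect_voids(mu_dixon, air_threshold)

  img_mr <- robust_normalize(g$values)
  img_pet <- robust_normalize(as_grid(nac_pet)$values)

  evidence <- outer_void_evidence(nac_pet, mu_dixon, air_threshold)
  # switch seed: PET breach evidence plus the envelope-interior voxels of
  # outer-class components (their 26-component continues into the free
  # background, which must not widen the switch field)
  outer_mask <- evidence
  for (oid in voids$components$id[voids$components$class == "outer"])
    outer_mask <- outer_mask | component_mask(voids, oid)
  w <- if (any(outer_mask))
    dilate_mm(outer_mask, g$spacing, params$switch_dilate_mm) else
      array(FALSE, dim(g$values))

  w_pet <- params$lambda_pet * (w != 0)
  w_mr <- params$lambda_mr * !(w != 0)

  # The PET data term uses fixed region levels determined from the PET
  # signal itself: the outside background level and a dim-tissue reference
  # (10th percentile of the breach-evidence region). Adaptive two-region
  # means would absorb the dim (attenuation-suppressed) void interior into
  # the background class and stall the contour there.
  env0 <- body_envelope(mu_dixon, air_threshold)
  far_out <- !dilate6(env0, 3L)
  c2p_fix <- if (any(far_out)) mean(img_pet[far_out]) else 0
  c1p_fix <- if (any(evidence))
    stats::quantile(img_pet[evidence], 0.10, names = FALSE)
  else mean(img_pet[env0 & !erode6(env0, 2L)])
  c1p_fix <- max(c1p_fix, c2p_fix + 0.05)

  naive_body <- fill_holes(label_components(g$values >= air_threshold, 26L) == 1L)
  # convention: phi > 0 inside the body
  phi <- -signed_distance(naive_body, g$spacing)

  ok_streak <- 0L
  converged <- FALSE
  energy <- numeric(0)
  it <- 0L
  nvox <- length(phi)
  eps_d <- 1.5 * min(g$spacing)
  while (it < params$max_iter) {
    it <- it + 1L
    inside <- phi > 0
    data_force <- array(0, dim(phi))
    for (ch in list(list(img_mr, w_mr, NULL), list(img_pet, w_pet,
                                                   c(c1p_fix, c2p_fix)))) {
      img <- ch[[1]]; wgt <- ch[[2]]; fixed <- ch[[3]]
      if (sum(wgt) == 0) next
      if (is.null(fixed)) {
        win <- wgt * inside; wout <- wgt * !inside
        c1 <- if (sum(win) > 0) sum(img * win) / sum(win) else 0
        c2 <- if (sum(wout) > 0) sum(img * wout) / sum(wout) else 0
      } else { c1 <- fixed[1]; c2 <- fixed[2] }
      data_force <- data_force + wgt * ((img - c2)^2 - (img - c1)^2)
    }
    force <- params$nu * cv_curvature(phi) + data_force
    delta <- eps_d / (pi * (phi^2 + eps_d^2))
    upd <- delta * force
    band <- abs(phi) <= 3 * eps_d
    m <- if (any(band)) stats::quantile(abs(upd[band]), 0.98, names = FALSE)
         else NA_real_
    if (!is.finite(m) || m < 1e-12) { converged <- TRUE; break }
    phi_new <- phi + params$dt * min(g$spacing) *
      pmin(pmax(upd / m, -1), 1)
    changed <- sum((phi_new > 0) != inside)
    phi <- phi_new
    if (it %% 10L == 0L)
      energy <- c(energy, cv_energy(phi > 0, img_mr, img_pet, w_mr, w_pet,
                                    params$nu))
    if (it %% params$reinit_interval == 0L)
      phi <- -signed_distance(phi > 0, g$spacing)
    if (it > params$min_iter && changed / nvox < params$tol) {
      ok_streak <- ok_streak + 1L
      if (ok_streak >= 5L) { converged <- TRUE; break }
    } else ok_streak <- 0L
  }
  if (!converged)
    warning("level set did not converge within max_iter", call. = FALSE)

  inside <- phi > 0
  lab <- label_components(inside, 26L)
  contour_mask <- fill_holes(lab == 1L)
  # the closing fills every voxel of background-connected void air that the
  # found contour encloses (the enclosed remainder of such components is the
  # signal void; the rest is true background outside the contour)
  filled_mask <- (voids$outer_air | voids$border_air) & contour_mask
  if (length(energy) > 1 && any(diff(energy) > 1e-6 * abs(energy[1])))
    message("level set: energy increased across some checkpoints ",
            "(reinitialization steps)")
  structure(list(contour_mask = contour_mask, filled_mask = filled_mask,
                 iterations = it, converged = converged, energy = energy),
            class = "contour_result")
}

#' @export
#' @method print contour_result
print.contour_result <- function(x, ...) {
  cat(sprintf("<contour_result> %d iterations, converged=%s, fills %d voxels\n",
              x$iterations, x$converged, sum(x$filled_mask)))
  invisible(x)
}

#' Close the contour and fill enclosed breached voids with soft tissue
#'
#' Void voxels that were background-connected air in the input map and lie
#' inside the found contour are set to exactly 0.1 cm^-1; all other voxels
#' are unchanged. The result is still a `"dixon"`-provenance map (the atlas
#' masking step is pending).
#'
#' @param mu_dixon [mu_map()].
#' @param contour a [evolve_contour()] result.
#' @param protect optional logical array of anatomical air (e.g. the warped
#'   atlas internal air) that should stay air.
#' @param seal_band_vox thickness (voxels) of the band under the contour in
#'   which residual background leaks override the protection: the closing
#'   must leave no void air path-connected to the outside, so where the
#'   warped air prior touches the recovered boundary the boundary wins.
#' @return a [mu_map()] with attribute `"filled_mask"`.
#' @export
close_and_fill <- function(mu_dixon, contour, protect = NULL,
                           seal_band_vox = 2L) {
  vals <- mu_dixon$grid$values
  cand <- contour$filled_mask & vals < MU_SOFT_TISSUE
  fill <- cand
  if (!is.null(protect)) fill <- fill & !protect
  vals[fill] <- MU_SOFT_TISSUE
  if (!is.null(protect) && any(cand & !fill)) {
    band <- contour$contour_mask &
      !erode6(contour$contour_mask, seal_band_vox)
    for (i in 1:3) {
      reach <- flood_from_border(vals < 0.005)
      leak <- cand & reach & band & vals < MU_SOFT_TISSUE
      if (!any(leak)) break
      vals[leak] <- MU_SOFT_TISSUE
      fill <- fill | leak
    }
  }
  sealed <- seal_surface_leaks(vals, cand, contour$contour_mask)
  vals <- sealed$vals
  fill <- fill | sealed$filled
  out <- mu_map(vox_grid(vals, mu_dixon$grid$spacing, mu_dixon$grid$origin),
                body_mask = mu_dixon$body_mask, provenance = "dixon")
  attr(out, "filled_mask") <- fill
  out
}
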