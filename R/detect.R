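# Detection of signal-void components on a mu-map and their topological
# classification (enclosed "inner" vs boundary-breaching "outer").

#' Derive the body envelope of a mu-map
#'
#' The anatomical envelope is the largest connected non-air component of the
#' map plus its internal cavities (hole filling). If the mu-map carries a
#' `body_mask`, that mask (hole-filled) is used instead.
#'
#' @param mu a [mu_map()].
#' @param air_threshold air threshold in cm^-1.
#' @return logical array (the solid envelope).
#' @export
body_envelope <- function(mu, air_threshold = 0.005) {
  if (!is.null(mu$body_mask)) return(fill_holes(mu$body_mask))
  lab <- label_components(mu$grid$values >= air_threshold, connectivity = 26L)
  if (max(lab) == 0L) return(array(FALSE, dim(mu$grid$values)))
  fill_holes(lab == 1L)
}

#' Detect signal-void components on a mu-map
#'
#' Labels connected components (default 26-connectivity) of sub-threshold
#' (air) voxels that intersect the body envelope. The free background air
#' outside the body is excluded, but a component that penetrates the envelope
#' (an outer-class void reaching background through a breach) is kept; its
#' voxel count and volume are measured inside the envelope only. Each
#' component is classified inner/outer by 6-connected reachability of
#' background air (see [classify_component()]).
#'
#' @param mu a [mu_map()].
#' @param air_threshold air threshold in cm^-1 (> 0); voids are voxels with
#'   `mu < air_threshold`. Default 0.005, well below fat and soft tissue.
#' @param envelope optional logical array overriding [body_envelope()].
#' @param connectivity void connectivity (26, 18 or 6). Default 26.
#' @return object of class `void_components`: a list with `label` (integer
#'   array, 0 = none; labels count only envelope-interior voxels),
#'   `components` (data.frame with `id`, `n_voxels`, `volume_ml`, `class`,
#'   bounding box columns), `air`, `background`, `envelope`.
#' @export
detect_voids <- function(mu, air_threshold = 0.005, envelope = NULL,
                         connectivity = 26L) {
  if (!is.finite(air_threshold) || air_threshold <= 0)
    stop("argument error: air_threshold must be > 0", call. = FALSE)
  g <- mu$grid
  d <- dim(g$values)
  air <- g$values < air_threshold
  if (is.null(envelope)) envelope <- body_envelope(mu, air_threshold)
  # background = air reachable from the grid border through air (6-conn);
  # computed over all air so breach channels are traversed
  background <- flood_from_border(air)

  lab_all <- label_components(air, connectivity = connectivity)
  inside <- air & envelope
  ids <- sort(unique(lab_all[inside]))
  ids <- ids[ids > 0]

  label <- array(0L, d)
  rows <- list()
  vml <- voxel_volume_ml(g)
  next_id <- 0L
  for (id in ids) {
    comp_inside <- lab_all == id & inside
    n <- sum(comp_inside)
    if (n == 0L) next
    next_id <- next_id + 1L
    label[comp_inside] <- next_id
    cls <- classify_component(lab_all == id, background)
    w <- which(comp_inside, arr.ind = TRUE)
    rows[[next_id]] <- data.frame(
      id = next_id, n_voxels = n, volume_ml = n * vml, class = cls,
      x0 = min(w[, 1]), x1 = max(w[, 1]), y0 = min(w[, 2]), y1 = max(w[, 2]),
      z0 = min(w[, 3]), z1 = max(w[, 3]))
  }
  comp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), n_voxels = integer(0), volume_ml = numeric(0),
               class = character(0), x0 = integer(0), x1 = integer(0),
               y0 = integer(0), y1 = integer(0), z0 = integer(0),
               z1 = integer(0))
  # order components by size (descending), relabel accordingly
  if (nrow(comp) > 1L) {
    ord <- order(comp$n_voxels, decreasing = TRUE)
    relab <- integer(nrow(comp)); relab[ord] <- seq_len(nrow(comp))
    newlab <- array(0L, d)
    pos <- label > 0L
    newlab[pos] <- relab[label[pos]]
    label <- newlab
    comp <- comp[ord, , drop = FALSE]
    comp$id <- seq_len(nrow(comp))
    rownames(comp) <- NULL
  }
  # union of the kept components' full air extent (including any part outside
  # the envelope, e.g. a breach channel) - used by the contour-closing fill;
  # outer_air restricts it to boundary-breaching (outer-class) components
  component_air <- array(FALSE, d)
  outer_air <- array(FALSE, d)
  for (k in seq_along(ids)) {
    m <- lab_all == ids[k]
    component_air <- component_air | m
    if (classify_component(m, background) == "outer")
      outer_air <- outer_air | m
  }
  # air belonging to 26-connected components that reach the grid border:
  # when a void breaches the body contour it merges with this set, and the
  # contour-closing step fills its part enclosed by the recovered contour
  blab <- integer(0)
  bids <- unique(c(lab_all[c(1, d[1]), , ], lab_all[, c(1, d[2]), ],
                   lab_all[, , c(1, d[3])]))
  bids <- bids[bids > 0]
  border_air <- if (length(bids)) array(lab_all %in% bids, d) else
    array(FALSE, d)
  structure(list(label = label, components = comp, air = air,
                 background = background, envelope = envelope,
                 component_air = component_air, outer_air = outer_air,
                 border_air = border_air, voxel_volume_ml = vml),
            class = "void_components")
}

#' @export
#' @method print void_components
print.void_components <- function(x, ...) {
  cat(sprintf("<void_components> %d component(s)\n", nrow(x$components)))
  if (nrow(x$components)) print(x$components[, c("id", "n_voxels", "volume_ml", "class")])
  invisible(x)
}

#' Classify a void component as inner or outer
#'
#' A component is `"outer"` iff it is path-connected through air voxels
#' (6-connectivity, the conservative breach test) to the background air
#' component touching the grid boundary; `"inner"` otherwise.
#'
#' @param comp_mask logical array of the component's voxels (the full air
#'   component, including any part outside the envelope).
#' @param background_air_mask logical array of border-reachable air
#'   (6-connected), e.g. from [detect_voids()].
#' @return `"inner"` or `"outer"`.
#' @export
classify_component <- function(comp_mask, background_air_mask) {
  if (!any(comp_mask)) stop("empty component", call. = FALSE)
  if (any(comp_mask & background_air_mask)) "outer" else "inner"
}

#' Volume of a void component in millilitres
#'
#' @param comp component mask (logical array) or a row id together with a
#'   [detect_voids()] result.
#' @param grid the [vox_grid()] the mask lives on.
#' @return voxel count times voxel volume, in mL.
#' @export
volume_ml <- function(comp, grid) {
  sum(comp != 0) * voxel_volume_ml(grid)
}

#' Binary mask of one detected component
#'
#' @param voids a [detect_voids()] result.
#' @param id component id.
#' @return logical array (envelope-interior voxels of the component).
#' @export
component_mask <- function(voids, id) voids$label == id

#' Write detection results (label mask + JSON component table)
#'
#' @param voids a [detect_voids()] result.
#' @param grid the source [vox_grid()] (for geometry).
#' @param path_nii label-mask output path; `path_json` component table path.
#' @return invisibly, the component table.
#' @export
write_voids <- function(voids, grid, path_nii, path_json) {
  write_volume(vox_grid(array(as.numeric(voids$label), dim(voids$label)),
                        grid$spacing, grid$origin), path_nii)
  jsonlite::write_json(voids$components, path_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(voids$components)
}
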