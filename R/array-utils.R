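# Low-level 3-D array morphology and filtering used across modules.
# All functions operate on plain arrays; grid-aware wrappers live with the
# callers.

# Shift an array by integer offsets, zero-filling exposed planes.
shift_array <- function(a, dx = 0L, dy = 0L, dz = 0L, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  lo <- pmax(1, 1 + c(dx, dy, dz))
  hi <- pmin(d, d + c(dx, dy, dz))
  if (any(lo > hi)) return(out)
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# 6-neighbour (face) binary dilation, n iterations.
dilate6 <- function(mask, n = 1L) {
  m <- mask != 0
  for (i in seq_len(n)) {
    m <- m |
      shift_array(m, 1L) | shift_array(m, -1L) |
      shift_array(m, 0L, 1L) | shift_array(m, 0L, -1L) |
      shift_array(m, 0L, 0L, 1L) | shift_array(m, 0L, 0L, -1L)
  }
  m
}

erode6 <- function(mask, n = 1L) !dilate6(!(mask != 0), n)

# Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
# Separable squared-distance transform, vectorized over scanlines (each axis
# pass is a brute-force lower envelope, O(n) scanline positions per offset).
distance_mm <- function(mask, spacing) {
  d <- dim(mask)
  BIG <- 1e12
  f <- array(ifelse(mask != 0, 0, BIG), d)
  for (ax in 1:3) {
    n <- d[ax]
    sp <- spacing[ax]
    m <- matrix(aperm(f, c(ax, setdiff(1:3, ax))), nrow = n)
    out <- m
    pos <- seq_len(n) * sp
    for (j in seq_len(n)) {
      out <- pmin(out, outer((pos - pos[j])^2, m[j, ], `+`))
    }
    perm <- c(ax, setdiff(1:3, ax))
    f <- aperm(array(out, d[perm]), order(perm))
  }
  sqrt(f)
}

# Binary dilation/erosion by a metric radius in mm (anisotropic-aware).
# The distance transform runs on a bounding box cropped to the reachable
# region for speed.
dilate_mm <- function(mask, spacing, radius_mm) {
  mask <- mask != 0
  if (radius_mm <= 0 || !any(mask)) return(mask)
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  pad <- ceiling(radius_mm / spacing) + 1
  lo <- pmax(apply(w, 2, min) - pad, 1)
  hi <- pmin(apply(w, 2, max) + pad, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- array(FALSE, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    distance_mm(sub, spacing) <= radius_mm
  out
}

erode_mm <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0) return(mask != 0)
  !dilate_mm(!(mask != 0), spacing, radius_mm)
}

# Flood fill of `open` (logical) from the grid border, 6-connectivity:
# the union of 6-connected components of `open` that touch the grid border.
flood_from_border <- function(open) {
  open <- open != 0
  lab <- label_components(open, connectivity = 6L)
  d <- dim(lab)
  ids <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                  lab[, , c(1, d[3])]))
  ids <- ids[ids > 0]
  if (!length(ids)) return(array(FALSE, d))
  array(lab %in% ids, d)
}

# Fill internal holes of a binary mask (holes = non-mask voxels not reachable
# from the border through non-mask voxels, 6-connectivity).
fill_holes <- function(mask) {
  mask <- mask != 0
  mask | !flood_from_border(!mask)
}

# Neighbourhood offsets (half-space, for undirected adjacency edges).
half_offsets <- function(connectivity = 26L) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  } else if (connectivity == 18L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) <= 2, ]
  }
  # keep one of each +/- pair
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs[keep, , drop = FALSE]
}

# Connected-component labeling of a logical array. Returns an integer array
# (0 = background) with components numbered in decreasing size order.
label_components <- function(mask, connectivity = 26L) {
  mask <- mask != 0
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  vert <- integer(length(mask))  # map voxel index -> vertex id
  vert[idx] <- seq_along(idx)
  offs <- half_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    sh <- shift_array(mask, offs$dx[k], offs$dy[k], offs$dz[k])
    both <- which(mask & sh)
    if (length(both)) {
      src <- both - offs$dx[k] - offs$dy[k] * d[1] - offs$dz[k] * d[1] * d[2]
      from <- c(from, vert[src]); to <- c(to, vert[both])
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(length(sizes)); relab[ord] <- seq_along(sizes)
  lab[idx] <- relab[comp$membership]
  lab
}

# Separable convolution with a symmetric 1-D kernel along one axis
# (zero-padded borders), via banded dense matrix multiply.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  half <- (length(kernel) - 1) / 2
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - 1 - half
    i <- seq_len(n)
    tgt <- i + off
    ok <- tgt >= 1 & tgt <= n
    K[cbind(i[ok], tgt[ok])] <- K[cbind(i[ok], tgt[ok])] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- K %*% m
  aperm(array(out, d[perm]), order(perm))
}

gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 3-D Gaussian smoothing with per-axis sigma given in mm.
gaussian_smooth <- function(a, sigma_mm, spacing) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  for (ax in 1:3) {
    sv <- sigma_mm[ax] / spacing[ax]
    if (sv > 1e-8) a <- conv_axis(a, gaussian_kernel1d(sv), ax)
  }
  a
}

# Dice overlap of two binary arrays.
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Block-mean downsampling by integer factors (for multi-resolution work).
downsample_mean <- function(a, f) {
  f <- rep(as.integer(f), length.out = 3)
  d <- dim(a)
  dd <- d %/% f
  a <- a[seq_len(dd[1] * f[1]), seq_len(dd[2] * f[2]), seq_len(dd[3] * f[3]),
         drop = FALSE]
  dim(a) <- c(f[1], dd[1], f[2], dd[2], f[3], dd[3])
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dd)
}
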