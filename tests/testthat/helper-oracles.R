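# Independent oracles used by the tests. These deliberately avoid the
# package's own implementation paths.

# Breadth-first-search flood-fill labeling of a logical 3-D array.
bfs_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1
      x <- rem %% d[1] + 1
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs$dx[k]; yy <- y + offs$dy[k]; zz <- z + offs$dz[k]
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
          next
        w <- xx + (yy - 1) * d[1] + (zz - 1) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# TRUE iff two integer labelings agree up to renaming of labels.
labels_equivalent <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  pos <- a > 0
  key <- paste(a[pos], b[pos])
  m <- unique(cbind(a[pos], b[pos]))
  !anyDuplicated(m[, 1]) && !anyDuplicated(m[, 2])
}

# Exact two-sided signed-rank p-value by enumeration of all sign vectors.
signrank_enum_p <- function(x, y) {
  dd <- x - y
  dd <- dd[dd != 0]
  n <- length(dd)
  r <- rank(abs(dd))
  V <- sum(r[dd > 0])
  centre <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats_all <- as.vector(signs %*% r)
  mean(abs(stats_all - centre) >= abs(V - centre) - 1e-9)
}

# Anti-aliased disc mu-map fixture on an in-plane grid (single slice):
# fractional voxel coverage by 4x4 supersampling.
disc_grid <- function(n = 96, spacing = 2.6, radius_mm = 60, value = 0.1,
                      nz = 1L) {
  g <- vox_grid(array(0, c(n, n, nz)), spacing = c(spacing, spacing, spacing))
  ax <- grid_axes(g)
  sub <- (seq_len(4) - 2.5) / 4 * spacing
  cov <- matrix(0, n, n)
  for (ox in sub) for (oy in sub) {
    cov <- cov + outer(ax[[1]] + ox, ax[[2]] + oy,
                       function(x, y) (x^2 + y^2 <= radius_mm^2) * 1)
  }
  cov <- cov / 16
  vals <- array(rep(cov * value, nz), c(n, n, nz))
  vox_grid(vals, g$spacing, g$origin)
}

total_variation <- function(a) {
  sum(abs(diff(a))) + sum(abs(aperm(apply(a, c(1, 3), diff), c(2, 1, 3)))) +
    sum(abs(apply(a, c(1, 2), diff)))
}
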