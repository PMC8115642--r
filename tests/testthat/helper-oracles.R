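# Independent brute-force oracles. These deliberately avoid the package's
# vectorised erosion/convolution machinery: every quantity is recomputed
# by direct per-voxel enumeration.

# In-plane disc offsets recomputed from first principles.
oracle_disc_offsets <- function(spacing2, radius) {
  ni <- ceiling(radius / spacing2[1]) + 1L
  nj <- ceiling(radius / spacing2[2]) + 1L
  g <- expand.grid(di = -ni:ni, dj = -nj:nj)
  keep <- sqrt((g$di * spacing2[1])^2 + (g$dj * spacing2[2])^2) <= radius + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# All valid ROI placements by scanning every candidate centre.
oracle_roi_placements <- function(mask, diameter = 3, axes = 1:3) {
  d <- dim(mask$data)
  out <- list()
  for (a in axes) {
    ip <- setdiff(1:3, a)
    off <- oracle_disc_offsets(mask$spacing[ip], diameter / 2)
    for (k in seq_len(d[a])) {
      for (r in seq_len(d[ip[1]])) for (cc in seq_len(d[ip[2]])) {
        idx <- rep(NA_integer_, 3)
        idx[a] <- k; idx[ip[1]] <- r; idx[ip[2]] <- cc
        if (!mask$data[idx[1], idx[2], idx[3]]) next
        ok <- TRUE
        for (m in seq_len(nrow(off))) {
          v <- idx
          v[ip[1]] <- r + off[m, 1]
          v[ip[2]] <- cc + off[m, 2]
          if (any(v < 1) || any(v > d) || !mask$data[v[1], v[2], v[3]]) {
            ok <- FALSE
            break
          }
        }
        if (ok)
          out[[length(out) + 1L]] <- c(plane_axis = a, slice = k,
                                       row = r, col = cc)
      }
    }
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}

# Member voxel coordinates of one placement (direct enumeration).
oracle_roi_members <- function(spacing, placement, diameter = 3) {
  a <- placement$plane_axis
  ip <- setdiff(1:3, a)
  off <- oracle_disc_offsets(spacing[ip], diameter / 2)
  vox <- matrix(NA_integer_, nrow(off), 3)
  vox[, a] <- placement$slice
  vox[, ip[1]] <- placement$row + off[, 1]
  vox[, ip[2]] <- placement$col + off[, 2]
  vox
}

# Exhaustive maximisation of the washout index over all placements,
# first-in-(plane, slice, row, col)-order tie-breaking.
oracle_max_wi <- function(pre, early, delay, mask, diameter = 3, axes = 1:3) {
  pl <- oracle_roi_placements(mask, diameter, axes)
  if (is.null(pl)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    vox <- oracle_roi_members(mask$spacing, p, diameter)
    mp <- mean(pre$data[vox]); me <- mean(early$data[vox])
    md <- mean(delay$data[vox])
    if (mp <= 0) next
    wi <- (me - md) / mp * 100
    if (is.null(best) || wi > best$wi + 0)
      best <- list(wi = wi, placement = p, si_pre = mp, si_early = me,
                   si_delay = md)
  }
  best$n_placements <- nrow(pl)
  best
}

# Longest in-plane diameter by full pairwise distances (no convex hull).
oracle_feret <- function(mask) {
  d <- dim(mask$data)
  best <- 0
  for (a in 1:3) {
    ip <- setdiff(1:3, a)
    sp <- mask$spacing[ip]
    for (k in seq_len(d[a])) {
      pts <- NULL
      for (r in seq_len(d[ip[1]])) for (cc in seq_len(d[ip[2]])) {
        idx <- rep(NA_integer_, 3)
        idx[a] <- k; idx[ip[1]] <- r; idx[ip[2]] <- cc
        if (mask$data[idx[1], idx[2], idx[3]])
          pts <- rbind(pts, c(r * sp[1], cc * sp[2]))
      }
      if (is.null(pts) || nrow(pts) < 2) next
      for (i in 1:(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
        dd <- sqrt(sum((pts[i, ] - pts[j, ])^2))
        if (dd > best) best <- dd
      }
    }
  }
  best
}

# Two-sided Fisher p by full enumeration of tables with fixed margins
# (sum-of-small-probabilities rule).
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Sphere mask helper used by several image tests.
make_sphere_mask <- function(dim, spacing, center, radius) {
  arr <- array(FALSE, dim)
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
    for (k in seq_len(dim[3])) {
      p <- c(i, j, k) * spacing
      if (sum((p - center)^2) <= radius^2 + 1e-9) arr[i, j, k] <- TRUE
    }
  lesion_mask(arr, spacing)
}
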