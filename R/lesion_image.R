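#' Construct a single-phase DCE volume
#'
#' A phase volume is one 3-D acquisition of a dynamic contrast-enhanced
#' study: the pre-contrast scan, the early phase (1--2 min after
#' injection) or the delayed phase (5--6 min). Voxel world coordinates
#' are `index * spacing` on an axis-aligned grid; oblique acquisitions
#' are expected to be resampled upstream.
#'
#' @param data Numeric 3-D array of signal intensities (arbitrary units).
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param phase One of `"pre"`, `"early"`, `"delay"`.
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(data, spacing, phase = c("pre", "early", "delay")) {
  phase <- match.arg(phase)
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data))
    stop("`data` must be a numeric 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing, phase = phase),
            class = "phase_volume")
}

#' Construct a binary lesion mask
#'
#' The mask lives on the same grid as its companion phase volumes and may
#' be empty (a radiological complete response has no enhancing voxels).
#'
#' @param data Logical (or 0/1 numeric) 3-D array; `TRUE` marks lesion.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  data <- array(as.logical(data), dim(data))
  if (anyNA(data)) stop("mask values must be 0/1 without NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "lesion_mask")
}

# Verify that phase volumes and mask share one grid (shape and spacing).
check_grid_alignment <- function(...) {
  objs <- list(...)
  ref_dim <- dim(objs[[1]]$data)
  ref_sp <- objs[[1]]$spacing
  for (o in objs[-1]) {
    dm <- dim(o$data)
    for (ax in 1:3) {
      if (dm[ax] != ref_dim[ax])
        stop("grid shape mismatch on axis ", ax, ": ", ref_dim[ax],
             " vs ", dm[ax])
      if (abs(o$spacing[ax] - ref_sp[ax]) > 1e-6)
        stop("voxel spacing mismatch on axis ", ax, ": ", ref_sp[ax],
             " vs ", o$spacing[ax])
    }
  }
  invisible(TRUE)
}

stop_classed <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# In-plane offsets (d_row, d_col) whose centre-to-centre distance is
# within `radius` mm, given the two in-plane spacings. Includes (0, 0).
# A 1e-9 mm tolerance guards exact-boundary float comparisons.
disc_offsets <- function(spacing2, radius) {
  ni <- floor(radius / spacing2[1] + 1e-9)
  nj <- floor(radius / spacing2[2] + 1e-9)
  g <- as.matrix(expand.grid(di = -ni:ni, dj = -nj:nj))
  d2 <- (g[, 1] * spacing2[1])^2 + (g[, 2] * spacing2[2])^2
  g[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

# out[r, c] = m[r + di, c + dj], out-of-range entries set to `fill`.
shift_matrix <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
  c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
  out
}

# Extract the 2-D slice at index k along plane axis a. Rows of the
# returned matrix follow the lower-numbered in-plane axis.
extract_slice <- function(arr, a, k) {
  switch(a,
         `1` = arr[k, , , drop = TRUE],
         `2` = arr[, k, , drop = TRUE],
         `3` = arr[, , k, drop = TRUE])
}

inplane_axes <- function(a) setdiff(1:3, a)

# Valid ROI centres in one slice: binary erosion of the mask slice by
# the disc structuring element (all member voxels must be mask members).
erode_slice <- function(mask2d, offsets) {
  valid <- matrix(TRUE, nrow(mask2d), ncol(mask2d))
  for (i in seq_len(nrow(offsets)))
    valid <- valid & shift_matrix(mask2d, offsets[i, 1], offsets[i, 2], FALSE)
  valid
}

# Disc sum of a signal slice: sum over offsets of shifted values.
# Correct at centres where the whole disc is in-grid (all valid centres).
disc_sum_slice <- function(sig2d, offsets) {
  s <- matrix(0, nrow(sig2d), ncol(sig2d))
  for (i in seq_len(nrow(offsets)))
    s <- s + shift_matrix(sig2d, offsets[i, 1], offsets[i, 2], 0)
  s
}

plane_axes_for <- function(planes = c("all", "axial")) {
  planes <- match.arg(planes)
  if (planes == "axial") 3L else 1:3
}

#' Enumerate all circular-ROI placements inside a lesion mask
#'
#' Reproduces the exhaustive version of the manual ROI search: a flat
#' circular ROI of the given diameter (default 3 mm) is placed, within a
#' single slice, at every voxel centre such that the whole disc --- every
#' in-plane voxel whose centre lies within `diameter/2` of the ROI centre
#' --- is contained in the mask. Slices are taken from all three
#' orthogonal plane families by default (the reading workstation allowed
#' reformatted planes), or only along axis 3 with `planes = "axial"`.
#'
#' @param mask A [lesion_mask()].
#' @param diameter ROI diameter in mm (default 3).
#' @param planes `"all"` (default) or `"axial"`.
#' @return A data frame with columns `plane_axis`, `slice`, `row`, `col`
#'   (voxel indices; `row`/`col` follow the two in-plane axes in
#'   ascending axis order), sorted by (plane, slice, row, col). The ROI
#'   diameter is attached as attribute `"diameter"`.
#' @section Errors: an empty mask signals a condition of class
#'   `washout_empty_mask`; a non-empty mask too small to contain any disc
#'   signals `washout_no_placement`.
#' @export
enumerate_roi_placements <- function(mask, diameter = 3,
                                     planes = c("all", "axial")) {
  stopifnot(inherits(mask, "lesion_mask"), diameter > 0)
  if (!any(mask$data))
    stop_classed("washout_empty_mask", "lesion mask is empty (no enhancing voxels)")
  axes <- plane_axes_for(planes)
  rows <- vector("list", 0L)
  for (a in axes) {
    ip <- inplane_axes(a)
    offsets <- disc_offsets(mask$spacing[ip], diameter / 2)
    for (k in seq_len(dim(mask$data)[a])) {
      sl <- extract_slice(mask$data, a, k)
      if (!any(sl)) next
      valid <- erode_slice(sl, offsets)
      if (!any(valid)) next
      w <- which(valid, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(plane_axis = a, slice = k, row = w[, 1], col = w[, 2])
    }
  }
  if (!length(rows))
    stop_classed("washout_no_placement",
                 sprintf("no %g mm ROI fits inside the lesion mask", diameter))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "diameter") <- diameter
  out
}

#' Member voxels of one ROI placement
#'
#' @param mask A [lesion_mask()] (or any object carrying `data` dims and
#'   `spacing`) defining the grid.
#' @param placement A single-row data frame or list with `plane_axis`,
#'   `slice`, `row`, `col`.
#' @param diameter ROI diameter in mm.
#' @return Integer matrix (one voxel per row, columns = array indices).
#' @export
roi_member_voxels <- function(mask, placement, diameter = 3) {
  a <- as.integer(placement$plane_axis)
  ip <- inplane_axes(a)
  offsets <- disc_offsets(mask$spacing[ip], diameter / 2)
  rr <- as.integer(placement$row) + offsets[, 1]
  cc <- as.integer(placement$col) + offsets[, 2]
  out <- matrix(0L, nrow(offsets), 3L)
  out[, a] <- as.integer(placement$slice)
  out[, ip[1]] <- rr
  out[, ip[2]] <- cc
  d <- dim(mask$data)
  if (any(out < 1L) || any(out[, 1] > d[1]) || any(out[, 2] > d[2]) ||
      any(out[, 3] > d[3]))
    stop("ROI placement extends beyond the image grid")
  out
}

#' Mean signal of an ROI placement
#'
#' @param volume A [phase_volume()].
#' @param placement As in [roi_member_voxels()].
#' @param diameter ROI diameter in mm.
#' @return The arithmetic mean of the member voxel signals.
#' @export
roi_mean_signal <- function(volume, placement, diameter = 3) {
  stopifnot(inherits(volume, "phase_volume"))
  vox <- roi_member_voxels(volume, placement, diameter)
  mean(volume$data[vox])
}

#' Maximal-washout-index ROI search inside a lesion
#'
#' Evaluates the washout index on the (per-phase mean signal of every)
#' fully contained circular-ROI placement in the mask and returns the
#' placement with the highest WI, mirroring the readers' instruction to
#' place multiple ROIs and keep the highest value. Ties are broken by
#' the deterministic enumeration order (plane, slice, row, col; first
#' wins). Placements whose mean pre-contrast signal is non-positive are
#' skipped with a warning.
#'
#' @param pre,early,delay [phase_volume()] objects on one grid.
#' @param mask A [lesion_mask()] on the same grid.
#' @param diameter ROI diameter in mm (default 3).
#' @param planes `"all"` or `"axial"`, see [enumerate_roi_placements()].
#' @param thresholds Curve-type thresholds, see [kinetic_thresholds()].
#' @param fallback `"none"` (default) signals `washout_no_placement` for
#'   lesions too small for the disc, mirroring the study's exclusion of
#'   undersized lesions; `"voxel"` falls back to single-voxel ROIs.
#' @return An object of class `lesion_kinetics`: a list with the winning
#'   `si_pre`, `si_early`, `si_delay`, `wi`, `enhancement_ratio`,
#'   `curve_class`, the winning `placement` and `n_placements`.
#' @export
lesion_max_wi <- function(pre, early, delay, mask, diameter = 3,
                          planes = c("all", "axial"),
                          thresholds = kinetic_thresholds(),
                          fallback = c("none", "voxel")) {
  stopifnot(inherits(pre, "phase_volume"), inherits(early, "phase_volume"),
            inherits(delay, "phase_volume"), inherits(mask, "lesion_mask"))
  fallback <- match.arg(fallback)
  check_grid_alignment(pre, early, delay, mask)
  if (!any(mask$data))
    stop_classed("washout_empty_mask", "lesion mask is empty (no enhancing voxels)")

  axes <- plane_axes_for(planes)
  best <- NULL
  best_wi <- -Inf
  n_placements <- 0L
  skipped_pre <- 0L

  for (a in axes) {
    ip <- inplane_axes(a)
    offsets <- disc_offsets(mask$spacing[ip], diameter / 2)
    k_roi <- nrow(offsets)
    for (k in seq_len(dim(mask$data)[a])) {
      msl <- extract_slice(mask$data, a, k)
      if (!any(msl)) next
      valid <- erode_slice(msl, offsets)
      if (!any(valid)) next
      n_placements <- n_placements + sum(valid)
      m_pre <- disc_sum_slice(extract_slice(pre$data, a, k), offsets) / k_roi
      m_early <- disc_sum_slice(extract_slice(early$data, a, k), offsets) / k_roi
      m_delay <- disc_sum_slice(extract_slice(delay$data, a, k), offsets) / k_roi
      bad_pre <- valid & m_pre <= 0
      if (any(bad_pre)) {
        skipped_pre <- skipped_pre + sum(bad_pre)
        valid <- valid & !bad_pre
        if (!any(valid)) next
      }
      wi <- (m_early - m_delay) / m_pre * 100
      wi[!valid] <- -Inf
      mx <- max(wi)
      if (mx > best_wi) {
        cand <- which(wi == mx & valid, arr.ind = TRUE)
        cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
        r <- cand[1, 1]; cc <- cand[1, 2]
        best_wi <- mx
        best <- list(plane_axis = a, slice = k, row = r, col = cc,
                     si_pre = m_pre[r, cc], si_early = m_early[r, cc],
                     si_delay = m_delay[r, cc])
      }
    }
  }

  if (skipped_pre > 0L)
    warning(skipped_pre,
            " ROI placement(s) skipped: non-positive mean pre-contrast signal")

  if (is.null(best)) {
    if (fallback == "voxel") {
      return(single_voxel_max_wi(pre, early, delay, mask, thresholds))
    }
    stop_classed("washout_no_placement",
                 sprintf("no %g mm ROI fits inside the lesion mask", diameter))
  }

  cls <- classify_curve(best$si_pre, best$si_early, best$si_delay, thresholds)
  structure(list(
    si_pre = best$si_pre, si_early = best$si_early, si_delay = best$si_delay,
    wi = cls$wi, enhancement_ratio = cls$enhancement_ratio,
    curve_class = as.character(cls$curve_class),
    placement = list(plane_axis = best$plane_axis, slice = best$slice,
                     row = best$row, col = best$col, diameter = diameter),
    n_placements = n_placements
  ), class = "lesion_kinetics")
}

# Fallback mode for lesions smaller than the ROI disc: every mask voxel
# is its own single-voxel ROI; ties resolved in array index order.
single_voxel_max_wi <- function(pre, early, delay, mask, thresholds) {
  vox <- which(mask$data)
  p <- pre$data[vox]; e <- early$data[vox]; d <- delay$data[vox]
  usable <- p > 0
  if (!any(usable))
    stop_classed("washout_no_placement",
                 "all single-voxel ROIs have non-positive pre-contrast signal")
  if (any(!usable))
    warning(sum(!usable),
            " voxel ROI(s) skipped: non-positive pre-contrast signal")
  wi <- (e - d) / p * 100
  wi[!usable] <- -Inf
  i <- which.max(wi)  # first maximum in array order
  co <- arrayInd(vox[i], dim(mask$data))
  cls <- classify_curve(p[i], e[i], d[i], thresholds)
  structure(list(
    si_pre = p[i], si_early = e[i], si_delay = d[i],
    wi = cls$wi, enhancement_ratio = cls$enhancement_ratio,
    curve_class = as.character(cls$curve_class),
    placement = list(plane_axis = NA_integer_, slice = co[3], row = co[1],
                     col = co[2], diameter = 0),
    n_placements = sum(usable)
  ), class = "lesion_kinetics")
}

#' @export
print.lesion_kinetics <- function(x, ...) {
  cat("Lesion kinetics (max-WI ROI search)\n")
  cat(sprintf("  WI: %.2f %%   enhancement ratio: %.1f %%   curve type: %s\n",
              x$wi, x$enhancement_ratio, x$curve_class))
  cat(sprintf("  SI (pre/early/delay): %.2f / %.2f / %.2f\n",
              x$si_pre, x$si_early, x$si_delay))
  if (!is.na(x$placement$plane_axis))
    cat(sprintf("  best ROI: plane axis %d, slice %d, (%d, %d); %d placements searched\n",
                x$placement$plane_axis, x$placement$slice,
                x$placement$row, x$placement$col, x$n_placements))
  invisible(x)
}

#' Lesion longest diameter
#'
#' For each of the three orthogonal plane families the maximal in-plane
#' Feret diameter is computed as the largest centre-to-centre distance
#' (in mm) between two mask voxels of any single slice; the result is the
#' maximum over the three families, matching a longest-diameter
#' measurement on reformatted sagittal/axial/coronal planes. An empty
#' mask has diameter 0, as does a single voxel (centre-to-centre
#' convention).
#'
#' @param mask A [lesion_mask()].
#' @return Longest diameter in mm.
#' @export
longest_diameter <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$data)) return(0)
  best <- 0
  for (a in 1:3) {
    ip <- inplane_axes(a)
    sp <- mask$spacing[ip]
    for (k in seq_len(dim(mask$data)[a])) {
      sl <- extract_slice(mask$data, a, k)
      w <- which(sl, arr.ind = TRUE)
      if (nrow(w) < 2L) next
      pts <- cbind(w[, 1] * sp[1], w[, 2] * sp[2])
      if (nrow(pts) > 3L) {
        hull <- grDevices::chull(pts)
        pts <- pts[hull, , drop = FALSE]
      }
      d <- max(stats::dist(pts))
      if (d > best) best <- d
    }
  }
  best
}

# Offsets of a closed ball of the given radius (mm) on the voxel grid.
ball_offsets <- function(spacing, radius) {
  rng <- lapply(1:3, function(a) {
    n <- floor(radius / spacing[a] + 1e-9)
    -n:n
  })
  g <- as.matrix(expand.grid(rng))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

# Morphological erosion of a binary 3-D mask by a ball (radius in mm).
# Voxels whose ball neighbourhood leaves the grid are eroded away.
erode_mask3d <- function(arr, spacing, radius) {
  off <- ball_offsets(spacing, radius)
  d <- dim(arr)
  coords <- which(arr, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(coords))
  for (i in seq_len(nrow(off))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + off[i, 1]
    nb[, 2] <- nb[, 2] + off[i, 2]
    nb[, 3] <- nb[, 3] + off[i, 3]
    inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    ok <- inb
    ok[inb] <- arr[nb[inb, , drop = FALSE]]
    keep <- keep & ok
    if (!any(keep)) break
  }
  out <- array(FALSE, d)
  if (any(keep)) out[coords[keep, , drop = FALSE]] <- TRUE
  out
}

# Number of 26-connected components of a binary 3-D mask.
count_components26 <- function(arr) {
  d <- dim(arr)
  vox <- which(arr)
  if (!length(vox)) return(0L)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  visited <- array(FALSE, d)
  coords <- arrayInd(vox, d)
  ncomp <- 0L
  for (i in seq_len(nrow(coords))) {
    v <- coords[i, , drop = FALSE]
    if (visited[v]) next
    ncomp <- ncomp + 1L
    visited[v] <- TRUE
    stack <- list(v[1, ])
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- sweep(off, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      sel <- arr[nb] & !visited[nb]
      nb <- nb[sel, , drop = FALSE]
      if (nrow(nb)) {
        visited[nb] <- TRUE
        for (j in seq_len(nrow(nb))) stack[[length(stack) + 1L]] <- nb[j, ]
      }
    }
  }
  ncomp
}

#' Shrinkage-pattern proxy for partial responders
#'
#' A computational stand-in for the readers' visual call on how a lesion
#' shrank under treatment. A follow-up lesion is `"dendritic"`
#' (fragmentation or uneven shrinkage) when it has more 26-connected
#' components than the baseline lesion, or when it is not fully contained
#' in the morphological interior of the baseline mask (baseline eroded by
#' a ball of `erosion_mm`); otherwise it is `"concentric"`. The caller is
#' expected to apply this only to lesions meeting the partial-response
#' size criterion; an empty follow-up mask is a complete response and the
#' pattern is undefined.
#'
#' @param baseline,followup [lesion_mask()] objects on one grid.
#' @param erosion_mm Erosion radius in mm defining the baseline interior
#'   (default 2).
#' @return `"concentric"` or `"dendritic"`.
#' @export
classify_shrinkage <- function(baseline, followup, erosion_mm = 2) {
  stopifnot(inherits(baseline, "lesion_mask"), inherits(followup, "lesion_mask"))
  check_grid_alignment(baseline, followup)
  if (!any(followup$data))
    stop_classed("washout_undefined_shrinkage",
                 "follow-up mask is empty: complete response, shrinkage pattern undefined")
  if (!any(baseline$data))
    stop("baseline mask is empty")
  nb <- count_components26(baseline$data)
  nf <- count_components26(followup$data)
  if (nf > nb) return("dendritic")
  interior <- erode_mask3d(baseline$data, baseline$spacing, erosion_mm)
  if (any(followup$data & !interior)) return("dendritic")
  "concentric"
}
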