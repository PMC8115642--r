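# Deterministic fan-out of one user seed into per-component child seeds.
# Counter-based so that adding a new draw never perturbs existing streams.
child_seed <- function(seed, idx) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + idx * 7919 + 17
  as.integer(s %% 2147483647)
}

# Truncated-normal sampler by inverse-CDF (exact, vectorised).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# One kinetic template: pre-contrast level plus enhancement ratio and
# washout index in percent; early/delayed signals follow from them.
kinetic_template <- function(si_pre, ratio, wi) {
  stopifnot(si_pre > 0, ratio >= 0)
  si_early <- si_pre * ratio / 100
  si_delay <- si_early - wi * si_pre / 100
  if (si_delay < 0)
    stop("template implies a negative delayed signal (wi too large for ratio)")
  list(si_pre = si_pre, ratio = ratio, wi = wi,
       si_early = si_early, si_delay = si_delay)
}

#' Specification of a multi-phase lesion phantom
#'
#' Describes a synthetic three-phase DCE study: a spherical (or
#' multi-focal) lesion embedded in non-enhancing background tissue, with
#' one kinetic template for the lesion bulk and optional spherical
#' subregions carrying their own templates (e.g. a planted fast-washout
#' focus inside a plateau lesion). Templates are triples
#' `(si_pre, ratio, wi)`: pre-contrast level, initial enhancement ratio
#' in percent and washout index in percent.
#'
#' @param dim Grid shape (three positive integers).
#' @param spacing Voxel sizes in mm.
#' @param lesion List with `center` (mm; default grid centre) and
#'   `radius` (mm).
#' @param lesion_template Kinetic template of the lesion bulk
#'   (default plateau: `si_pre = 200`, `ratio = 180`, `wi = 0`).
#' @param subregions List of lists, each with `center` (mm), `radius`
#'   (mm) and `si_pre`, `ratio`, `wi`. Subregions must be pairwise
#'   disjoint and inside the lesion.
#' @param tissue_template Template of non-lesion tissue
#'   (default `si_pre = 300`, `ratio = 110`, `wi = 0`).
#' @param noise_sd Gaussian noise standard deviation in signal units.
#' @param roi_diameter ROI diameter (mm) used to flag which planted
#'   subregions are recoverable by the disc search.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32, 32, 20), spacing = c(1, 1, 1),
                         lesion = list(center = NULL, radius = 10),
                         lesion_template = list(si_pre = 200, ratio = 180, wi = 0),
                         subregions = list(),
                         tissue_template = list(si_pre = 300, ratio = 110, wi = 0),
                         noise_sd = 0, roi_diameter = 3, seed = 1) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), length(spacing) == 3L,
            all(spacing > 0), noise_sd >= 0, lesion$radius > 0)
  if (is.null(lesion$center)) lesion$center <- dim * spacing / 2
  for (s in subregions) {
    stopifnot(!is.null(s$center), !is.null(s$radius), s$radius > 0)
    if (sqrt(sum((s$center - lesion$center)^2)) + s$radius >
        lesion$radius + 1e-9)
      stop("subregion extends outside the lesion sphere")
  }
  if (length(subregions) > 1L) {
    for (i in seq_along(subregions)[-1]) for (j in seq_len(i - 1L)) {
      si <- subregions[[i]]; sj <- subregions[[j]]
      if (sqrt(sum((si$center - sj$center)^2)) < si$radius + sj$radius - 1e-9)
        stop("subregions must be pairwise disjoint")
    }
  }
  structure(list(dim = dim, spacing = as.numeric(spacing), lesion = lesion,
                 lesion_template = lesion_template, subregions = subregions,
                 tissue_template = tissue_template, noise_sd = noise_sd,
                 roi_diameter = roi_diameter, seed = seed),
            class = "phantom_spec")
}

#' Simulate a three-phase lesion phantom
#'
#' Builds the pre/early/delayed phase volumes and the lesion mask for a
#' [phantom_spec()], adding seeded Gaussian noise per phase. The ground
#' truth records every planted template, whether each region can host a
#' fully contained ROI disc of `roi_diameter`, the overall planted
#' maximal WI and the maximal WI among disc-recoverable regions (the
#' value an exhaustive noise-free ROI search attains when the top region
#' is recoverable).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `pre`, `early`, `delay` ([phase_volume()]),
#'   `mask` ([lesion_mask()]) and `truth`.
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim; sp <- spec$spacing
  cx <- (seq_len(d[1])) * sp[1]
  cy <- (seq_len(d[2])) * sp[2]
  cz <- (seq_len(d[3])) * sp[3]
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  dist2 <- function(center)
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2

  inside_lesion <- dist2(spec$lesion$center) <= spec$lesion$radius^2 + 1e-9

  tt <- kinetic_template(spec$tissue_template$si_pre,
                         spec$tissue_template$ratio, spec$tissue_template$wi)
  lt <- kinetic_template(spec$lesion_template$si_pre,
                         spec$lesion_template$ratio, spec$lesion_template$wi)
  pre <- array(tt$si_pre, d); early <- array(tt$si_early, d)
  delay <- array(tt$si_delay, d)
  pre[inside_lesion] <- lt$si_pre
  early[inside_lesion] <- lt$si_early
  delay[inside_lesion] <- lt$si_delay

  # a region is disc-recoverable when a whole ROI disc fits inside it
  # (conservative: disc radius plus one voxel of slack in every direction)
  disc_fits <- function(radius) radius >= spec$roi_diameter / 2 + max(sp)

  regions <- list(list(name = "lesion", wi = lt$wi,
                       recoverable = disc_fits(spec$lesion$radius)))
  for (i in seq_along(spec$subregions)) {
    s <- spec$subregions[[i]]
    st <- kinetic_template(s$si_pre, s$ratio, s$wi)
    inside <- dist2(s$center) <= s$radius^2 + 1e-9
    pre[inside] <- st$si_pre
    early[inside] <- st$si_early
    delay[inside] <- st$si_delay
    regions[[length(regions) + 1L]] <-
      list(name = paste0("subregion_", i), wi = st$wi,
           recoverable = disc_fits(s$radius))
  }

  if (spec$noise_sd > 0) {
    nv <- prod(d)
    set.seed(child_seed(spec$seed, 1L))
    pre <- pre + stats::rnorm(nv, 0, spec$noise_sd)
    set.seed(child_seed(spec$seed, 2L))
    early <- early + stats::rnorm(nv, 0, spec$noise_sd)
    set.seed(child_seed(spec$seed, 3L))
    delay <- delay + stats::rnorm(nv, 0, spec$noise_sd)
    early[early < 0] <- 0
    delay[delay < 0] <- 0
  }

  wi_all <- vapply(regions, `[[`, numeric(1), "wi")
  rec <- vapply(regions, `[[`, logical(1), "recoverable")
  truth <- list(
    regions = regions,
    wi_max_planted = max(wi_all),
    wi_max_recoverable = if (any(rec)) max(wi_all[rec]) else NA_real_,
    top_region_recoverable = rec[which.max(wi_all)]
  )

  list(pre = phase_volume(pre, sp, "pre"),
       early = phase_volume(early, sp, "early"),
       delay = phase_volume(delay, sp, "delay"),
       mask = lesion_mask(inside_lesion, sp),
       truth = truth)
}
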