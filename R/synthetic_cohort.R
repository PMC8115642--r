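#' Specification of a synthetic neoadjuvant TNBC cohort
#'
#' Defines the generative model for a per-patient cohort table with the
#' distributional structure of a neoadjuvant-treated TNBC population:
#' residual-cancer-burden classes with the observed class frequencies,
#' lesion sizes shrinking under treatment, washout indices that separate
#' the pCR group from residual-disease groups at the mid and
#' post-treatment MRIs, curve types derived from the sampled kinetics
#' through the fast-washout thresholds, and exponential distant
#' disease-free survival with group-specific hazards whose ratio between
#' residual disease without and with fast washout defaults to 0.10.
#'
#' The washout-index and size distributions are illustrative truncated
#' normals chosen to mirror the qualitative group separation of such
#' cohorts; they are configuration, not estimates.
#'
#' @param n Number of patients (default 74).
#' @param rcb_probs Probabilities of RCB classes 0--3
#'   (default `c(0.324, 0.230, 0.365, 0.081)`).
#' @param lesion_type_probs Probabilities of mass / NME / mixed
#'   morphology at baseline.
#' @param p_aggressive Probability that a residual-disease patient has
#'   the aggressive (recurrence-prone, persistently washing-out) kinetic
#'   profile.
#' @param wi_params Per-timepoint, per-profile mean/sd of the washout
#'   index (percent); see source for the layout.
#' @param ratio_params Per-profile mean/sd of the initial enhancement
#'   ratio (percent), truncated below at 105.
#' @param p_size0 Probability that the lesion has vanished (size 0) at
#'   mid / post, per response group.
#' @param hazards Exponential DDFS hazards (per year) for the three
#'   survival groups at the post-treatment MRI.
#' @param censor_range Uniform range (years) of the censoring time.
#' @param thresholds Curve-type thresholds, see [kinetic_thresholds()].
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 74,
                        rcb_probs = c(0.324, 0.230, 0.365, 0.081),
                        lesion_type_probs = c(mass = 0.743, nme = 0.108,
                                              mixed = 0.149),
                        p_aggressive = 0.35,
                        wi_params = list(
                          pre = list(pcr = c(25, 10), rd = c(25, 10),
                                     rd_agg = c(28, 10)),
                          mid = list(pcr = c(-5, 7), rd = c(12, 8),
                                     rd_agg = c(22, 8)),
                          post = list(pcr = c(-8, 6), rd = c(6, 7),
                                      rd_agg = c(20, 8))
                        ),
                        ratio_params = list(pcr = c(150, 30), rd = c(175, 40),
                                            rd_agg = c(280, 40)),
                        p_size0 = list(mid = c(pcr = 0.07, rd = 0.01),
                                       post = c(pcr = 0.52, rd = 0.05)),
                        hazards = c(cr_mri = 0.003, rd_fast_washout = 0.07,
                                    rd_other = 0.007),
                        censor_range = c(0.67, 12.5),
                        thresholds = kinetic_thresholds(),
                        seed = 1) {
  stopifnot(n >= 1, length(rcb_probs) == 4L,
            abs(sum(rcb_probs) - 1) < 1e-8, all(rcb_probs >= 0),
            abs(sum(lesion_type_probs) - 1) < 1e-8,
            all(hazards > 0), length(censor_range) == 2L,
            censor_range[1] > 0, censor_range[2] > censor_range[1],
            p_aggressive >= 0, p_aggressive <= 1)
  structure(list(n = as.integer(n), rcb_probs = rcb_probs,
                 lesion_type_probs = lesion_type_probs,
                 p_aggressive = p_aggressive, wi_params = wi_params,
                 ratio_params = ratio_params, p_size0 = p_size0,
                 hazards = hazards, censor_range = censor_range,
                 thresholds = thresholds, seed = seed),
            class = "cohort_spec")
}

#' Simulate a synthetic patient cohort
#'
#' Draws a full cohort table (schema of [read_cohort()]) from a
#' [cohort_spec()]. Pathology first: RCB class (index drawn within the
#' class band, cut-points 1.36 and 3.28), pCR defined as RCB class 0.
#' Residual-disease patients receive a latent aggressive profile with
#' probability `p_aggressive`; washout indices, enhancement ratios and
#' lesion sizes are then drawn per timepoint conditional on the profile,
#' curve types derived through [classify_curve()], and DDFS simulated as
#' exponential with the hazard of the post-treatment survival group
#' under independent uniform censoring. Fully reproducible given the
#' spec seed; each sampling block uses its own child seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with the cohort schema columns plus the latent
#'   `profile` attached as attribute `"profile"`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n

  set.seed(child_seed(spec$seed, 1L))
  rcb_class <- sample(0:3, n, replace = TRUE, prob = spec$rcb_probs)
  pcr <- rcb_class == 0L

  set.seed(child_seed(spec$seed, 2L))
  rcb_index <- numeric(n)
  rcb_index[rcb_class == 1L] <- stats::runif(sum(rcb_class == 1L), 0.30, 1.36)
  rcb_index[rcb_class == 2L] <- stats::runif(sum(rcb_class == 2L), 1.36, 3.28)
  rcb_index[rcb_class == 3L] <- stats::runif(sum(rcb_class == 3L), 3.28, 5.50)

  set.seed(child_seed(spec$seed, 3L))
  lesion_type <- sample(names(spec$lesion_type_probs), n, replace = TRUE,
                        prob = spec$lesion_type_probs)

  set.seed(child_seed(spec$seed, 4L))
  profile <- ifelse(pcr, "pcr",
                    ifelse(stats::runif(n) < spec$p_aggressive,
                           "rd_agg", "rd"))

  # pathological tumour size tracks the RCB index with noise
  set.seed(child_seed(spec$seed, 5L))
  pt_mm <- ifelse(pcr, 0, pmax(0, rcb_index * 12 + stats::rnorm(n, 0, 5)))

  set.seed(child_seed(spec$seed, 6L))
  size_pre <- pmin(80, pmax(12.5, stats::rlnorm(n, log(30), 0.35)))

  draw_size <- function(idx_seed, prev, p0, shrink_lo, shrink_hi) {
    set.seed(child_seed(spec$seed, idx_seed))
    gone <- stats::runif(n) < p0
    sz <- prev * stats::runif(n, shrink_lo, shrink_hi)
    ifelse(gone, 0, pmax(1, sz))
  }
  p0_mid <- ifelse(pcr, spec$p_size0$mid["pcr"], spec$p_size0$mid["rd"])
  lo_mid <- ifelse(profile == "pcr", 0.15, ifelse(profile == "rd_agg", 0.6, 0.4))
  hi_mid <- ifelse(profile == "pcr", 0.55, ifelse(profile == "rd_agg", 1.0, 0.8))
  size_mid <- draw_size(7L, size_pre, p0_mid, lo_mid, hi_mid)
  p0_post <- ifelse(pcr, spec$p_size0$post["pcr"], spec$p_size0$post["rd"])
  lo_post <- ifelse(profile == "pcr", 0.05, ifelse(profile == "rd_agg", 0.45, 0.2))
  hi_post <- ifelse(profile == "pcr", 0.35, ifelse(profile == "rd_agg", 0.9, 0.6))
  size_post <- draw_size(8L, size_mid + (size_mid == 0) * 1e-9, p0_post,
                         lo_post, hi_post)
  size_post[size_mid == 0] <- 0

  draw_wi <- function(idx_seed, tp, lower) {
    set.seed(child_seed(spec$seed, idx_seed))
    par <- spec$wi_params[[tp]]
    m <- vapply(profile, function(p) par[[p]][1], numeric(1))
    s <- vapply(profile, function(p) par[[p]][2], numeric(1))
    rtnorm(n, m, s, lower = lower)
  }
  wi_pre <- draw_wi(9L, "pre", 0.5)
  wi_mid <- draw_wi(10L, "mid", -Inf)
  wi_post <- draw_wi(11L, "post",
                     ifelse(profile == "rd_agg", 0.5, -Inf))

  set.seed(child_seed(spec$seed, 12L))
  rp <- spec$ratio_params
  rm <- vapply(profile, function(p) rp[[p]][1], numeric(1))
  rs <- vapply(profile, function(p) rp[[p]][2], numeric(1))
  ratio_pre <- rtnorm(n, pmax(rm, 220), rs, lower = 105)
  set.seed(child_seed(spec$seed, 13L))
  ratio_mid <- rtnorm(n, rm, rs, lower = 105)
  set.seed(child_seed(spec$seed, 14L))
  ratio_post <- rtnorm(n, rm, rs, lower = 105)

  curve_from <- function(size, wi, ratio) {
    wi <- pmin(wi, ratio - 1e-6)  # keep the implied delayed signal >= 0
    cls <- as.character(classify_curve(100, ratio, ratio - wi,
                                       spec$thresholds)$curve_class)
    out <- ifelse(size == 0, "none", cls)
    out
  }
  curve_pre <- curve_from(size_pre, wi_pre, ratio_pre)
  curve_mid <- curve_from(size_mid, wi_mid, ratio_mid)
  curve_post <- curve_from(size_post, wi_post, ratio_post)
  wi_pre[size_pre == 0] <- NA_real_
  wi_mid[size_mid == 0] <- NA_real_
  wi_post[size_post == 0] <- NA_real_

  grp <- survival_group(size_post, curve_post)
  lam <- spec$hazards[as.character(grp)]
  set.seed(child_seed(spec$seed, 15L))
  t_event <- stats::rexp(n, rate = lam)
  set.seed(child_seed(spec$seed, 16L))
  t_cens <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
  ddfs_years <- pmin(t_event, t_cens)
  ddfs_event <- t_event <= t_cens

  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    lesion_type = lesion_type,
    rcb_index = rcb_index,
    rcb_class = rcb_class,
    pcr = pcr,
    pt_mm = pt_mm,
    size_pre = size_pre, size_mid = size_mid, size_post = size_post,
    wi_pre = wi_pre, wi_mid = wi_mid, wi_post = wi_post,
    curve_pre = curve_pre, curve_mid = curve_mid, curve_post = curve_post,
    ddfs_years = ddfs_years,
    ddfs_event = ddfs_event,
    stringsAsFactors = FALSE
  )
  attr(out, "profile") <- profile
  validate_cohort(out)
  out
}

#' Simulate two-group exponential survival data
#'
#' Minimal generator for survival property checks: two groups with
#' proportional exponential hazards (`hazard` for the reference group,
#' `hazard * hr` for the other) under independent uniform censoring.
#'
#' @param n Total sample size (split evenly).
#' @param hr True hazard ratio of group `"b"` versus group `"a"`.
#' @param hazard Reference-group hazard (events per year).
#' @param censor_range Uniform censoring range in years.
#' @param seed Integer seed.
#' @return Data frame with `time`, `event`, `group`.
#' @export
simulate_ddfs_groups <- function(n = 400, hr = 0.10, hazard = 0.25,
                                 censor_range = c(1, 10), seed = 1) {
  stopifnot(n >= 4, hr > 0, hazard > 0)
  na <- n %/% 2L
  nb <- n - na
  group <- factor(rep(c("a", "b"), c(na, nb)))
  rate <- ifelse(group == "a", hazard, hazard * hr)
  set.seed(child_seed(seed, 1L))
  t_event <- stats::rexp(n, rate)
  set.seed(child_seed(seed, 2L))
  t_cens <- stats::runif(n, censor_range[1], censor_range[2])
  data.frame(time = pmin(t_event, t_cens),
             event = t_event <= t_cens,
             group = group)
}
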