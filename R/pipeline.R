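#' Default analysis configuration
#'
#' Central knobs of the pipeline: curve-type thresholds (strict 200\%
#' enhancement, inclusive 10\% washout), the 20 mm size stratification
#' cut, ROI diameter and plane families for the max-WI search, the
#' fallback policy for lesions too small for the ROI disc, and the
#' erosion radius of the shrinkage-pattern proxy.
#'
#' @param enhancement_min,washout_min Curve thresholds, see
#'   [kinetic_thresholds()].
#' @param size_cut_mm Size stratification cut-off in mm (strict `<` vs
#'   `>=`).
#' @param roi_diameter ROI diameter in mm.
#' @param roi_planes `"all"` or `"axial"`.
#' @param roi_fallback `"none"` or `"voxel"`, see [lesion_max_wi()].
#' @param shrink_erosion_mm Erosion radius of [classify_shrinkage()].
#' @return A named list of class `washout_config`.
#' @export
default_config <- function(enhancement_min = 200, washout_min = 10,
                           size_cut_mm = 20, roi_diameter = 3,
                           roi_planes = c("all", "axial"),
                           roi_fallback = c("none", "voxel"),
                           shrink_erosion_mm = 2) {
  stopifnot(size_cut_mm > 0, roi_diameter > 0, shrink_erosion_mm > 0)
  structure(list(
    thresholds = kinetic_thresholds(enhancement_min, washout_min),
    size_cut_mm = size_cut_mm,
    roi_diameter = roi_diameter,
    roi_planes = match.arg(roi_planes),
    roi_fallback = match.arg(roi_fallback),
    shrink_erosion_mm = shrink_erosion_mm
  ), class = "washout_config")
}

as_volume <- function(x, phase) {
  if (is.character(x)) read_phase_volume(x, phase) else x
}

#' Analyse one lesion from three-phase volumes and a mask
#'
#' End-to-end lesion report: longest diameter, maximal washout index
#' with its ROI location, enhancement ratio, curve type and the combined
#' imaging predictor of pathological response. An empty mask (no
#' enhancing lesion) yields size 0, curve class `"none"` and a positive
#' response prediction.
#'
#' @param pre,early,delay [phase_volume()] objects or NIfTI file paths.
#' @param mask A [lesion_mask()] or NIfTI file path.
#' @param config See [default_config()].
#' @return A list with `size_mm`, `wi`, `enhancement_ratio`,
#'   `curve_class`, `predicts_response`, `roi` (winning placement or
#'   `NULL`) and `n_placements`.
#' @export
analyze_lesion <- function(pre, early, delay, mask,
                           config = default_config()) {
  pre <- as_volume(pre, "pre")
  early <- as_volume(early, "early")
  delay <- as_volume(delay, "delay")
  if (is.character(mask)) mask <- read_lesion_mask(mask)
  check_grid_alignment(pre, early, delay, mask)

  if (!any(mask$data)) {
    return(list(size_mm = 0, wi = NA_real_, enhancement_ratio = NA_real_,
                curve_class = "none", predicts_response = TRUE,
                roi = NULL, n_placements = 0L))
  }
  size_mm <- longest_diameter(mask)
  lk <- lesion_max_wi(pre, early, delay, mask,
                      diameter = config$roi_diameter,
                      planes = config$roi_planes,
                      thresholds = config$thresholds,
                      fallback = config$roi_fallback)
  list(size_mm = size_mm, wi = lk$wi,
       enhancement_ratio = lk$enhancement_ratio,
       curve_class = lk$curve_class,
       predicts_response = unname(predict_pathresponse(size_mm, lk$wi)),
       roi = lk$placement, n_placements = lk$n_placements)
}

# Diagnostic-performance block of the cohort report: both predictors x
# both pathological endpoints x both on-treatment timepoints.
cohort_diagnostics <- function(cohort) {
  endpoints <- list(pcr = cohort$pcr,
                    rcb1 = !is.na(cohort$rcb_class) & cohort$rcb_class <= 1)
  rows <- list()
  for (tp in c("mid", "post")) {
    size <- cohort[[paste0("size_", tp)]]
    wi <- cohort[[paste0("wi_", tp)]]
    pred_wi <- rep(NA, nrow(cohort))
    ok <- !is.na(size)
    pred_wi[ok] <- predict_pathresponse(size[ok], wi[ok])
    pred_size <- ifelse(is.na(size), NA, size == 0)
    for (ep in names(endpoints)) {
      for (pr in c("wi_or_size0", "size0")) {
        pred <- if (pr == "wi_or_size0") pred_wi else pred_size
        cc <- confusion_counts(pred, endpoints[[ep]])
        perf <- suppressWarnings(
          diagnostic_performance(cc$tp, cc$fp, cc$fn, cc$tn))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(endpoint = ep, predictor = pr, timepoint = tp,
                     tp_ = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                     n_excluded = cc$n_excluded),
          perf)
      }
    }
  }
  do.call(rbind, rows)
}

# Stratified Fisher tests of the cohort report (imaging stratum vs
# pCR/RD), mirroring the six bundled reference strata.
cohort_fisher <- function(cohort, size_cut_mm) {
  pcr <- cohort$pcr
  out <- list()
  add <- function(name, stratum, keep) {
    k <- keep & !is.na(stratum) & !is.na(pcr)
    s <- stratum[k]; p <- pcr[k]
    tab <- c(a = sum(s & p), b = sum(s & !p),
             c = sum(!s & p), d = sum(!s & !p))
    out[[name]] <<- list(table = tab, n_excluded = sum(!k),
                         p_value = fisher_exact_two_sided(tab["a"], tab["b"],
                                                          tab["c"], tab["d"]))
  }
  add("lesion_type", cohort$lesion_type == "mass", rep(TRUE, nrow(cohort)))
  for (tp in c("pre", "mid", "post")) {
    size <- cohort[[paste0("size_", tp)]]
    add(paste0("size_", tp), !is.na(size) & size < size_cut_mm, !is.na(size))
  }
  for (tp in c("mid", "post")) {
    curve <- cohort[[paste0("curve_", tp)]]
    keep <- !is.na(curve) & curve %in% c("fast_washout", "other")
    add(paste0("curve_", tp), curve == "fast_washout", keep)
  }
  out
}

# Spearman correlations of imaging quantities against pathology.
cohort_correlations <- function(cohort) {
  rows <- list()
  add <- function(name, x, y, subset = rep(TRUE, length(x))) {
    k <- subset & !is.na(x) & !is.na(y)
    res <- if (sum(k) >= 3) spearman_rho(x[k], y[k])
           else list(rho = NA_real_, p_value = NA_real_, n = sum(k))
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = name, rho = res$rho, p_value = res$p_value, n = res$n)
  }
  rd <- !cohort$pcr
  for (tp in c("mid", "post")) {
    add(paste0("wi_", tp, "_vs_rcb"), cohort[[paste0("wi_", tp)]],
        cohort$rcb_index)
    add(paste0("size_", tp, "_vs_rcb"), cohort[[paste0("size_", tp)]],
        cohort$rcb_index)
    # pathological size correlation is evaluated in the RD group only
    add(paste0("size_", tp, "_vs_pt"), cohort[[paste0("size_", tp)]],
        cohort$pt_mm, rd)
  }
  do.call(rbind, rows)
}

# Pairwise t-tests of WI between response groups per timepoint
# (pCR vs RD without recurrence, pCR vs RD with recurrence,
#  RD without vs with recurrence).
cohort_wi_tests <- function(cohort) {
  grp <- ifelse(cohort$pcr, "pcr",
                ifelse(cohort$ddfs_event, "rd_recur", "rd_norecur"))
  rows <- list()
  for (tp in c("pre", "mid", "post")) {
    wi <- cohort[[paste0("wi_", tp)]]
    for (pair in list(c("pcr", "rd_norecur"), c("pcr", "rd_recur"),
                      c("rd_norecur", "rd_recur"))) {
      x <- wi[grp == pair[1] & !is.na(wi)]
      y <- wi[grp == pair[2] & !is.na(wi)]
      res <- if (length(x) >= 2 && length(y) >= 2)
        suppressWarnings(two_sample_t(x, y))
      else list(t = NA_real_, p_value = NA_real_,
                mean_x = mean(x), mean_y = mean(y))
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tp, group1 = pair[1], group2 = pair[2],
        n1 = length(x), n2 = length(y),
        mean1 = res$mean_x, mean2 = res$mean_y,
        t = res$t, p_value = res$p_value)
    }
  }
  do.call(rbind, rows)
}

# Survival block: three-group KM + log-rank, and the Cox contrast of
# residual disease without vs with fast washout, per timepoint.
cohort_survival <- function(cohort) {
  out <- list()
  for (tp in c("mid", "post")) {
    dd <- build_ddfs(cohort, timepoint = tp)
    block <- list(n = nrow(dd), n_excluded = attr(dd, "n_excluded"))
    block$events_by_group <- tapply(dd$event, dd$group, sum)
    block$n_by_group <- table(dd$group)
    block$km <- lapply(split(dd, dd$group), function(g)
      if (nrow(g)) km_estimate(g$time, g$event) else NULL)
    block$five_year <- vapply(block$km, function(k)
      if (is.null(k)) NA_real_ else survival_at(k, 5), numeric(1))
    if (nlevels(droplevels(dd$group)) >= 2)
      block$log_rank <- log_rank(dd$time, dd$event, dd$group)
    rdsub <- dd[dd$group %in% c("rd_fast_washout", "rd_other"), ]
    rdsub$group <- droplevels(rdsub$group)
    if (nlevels(rdsub$group) == 2 && sum(rdsub$event) >= 1) {
      # contrast: rd_other vs rd_fast_washout (HR < 1 = protective)
      block$cox_rd_other_vs_fast <- suppressWarnings(
        cox_ph(rdsub$time, rdsub$event, rdsub$group))
    }
    out[[tp]] <- block
  }
  out
}

#' Full cohort analysis report
#'
#' Runs the whole statistical battery on a cohort table: diagnostic
#' performance of the imaging predictors against pCR and RCB class <= I
#' at the mid- and post-treatment MRIs, stratified Fisher tests
#' (morphology, 20 mm size strata, curve type) of pCR vs residual
#' disease, Spearman correlations of WI and size against the RCB index
#' and pathological size, pairwise t-tests of WI between response
#' groups, and the distant disease-free survival block (Kaplan-Meier
#' per group, log-rank, Cox hazard ratio of residual disease without vs
#' with fast washout). Every block counts its per-analysis exclusions.
#'
#' @param cohort A cohort data frame or path to a delimited cohort file.
#' @param config See [default_config()].
#' @return A list of class `cohort_report` with components
#'   `diagnostics`, `fisher`, `correlations`, `wi_tests`, `survival`.
#' @export
cohort_report <- function(cohort, config = default_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  structure(list(
    diagnostics = cohort_diagnostics(cohort),
    fisher = cohort_fisher(cohort, config$size_cut_mm),
    correlations = cohort_correlations(cohort),
    wi_tests = cohort_wi_tests(cohort),
    survival = cohort_survival(cohort)
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort analysis report\n\n")
  cat("Diagnostic performance (percent):\n")
  d <- x$diagnostics
  d[c("sensitivity", "specificity", "ppv", "npv", "accuracy")] <-
    lapply(d[c("sensitivity", "specificity", "ppv", "npv", "accuracy")],
           round, 1)
  print(d, row.names = FALSE)
  cat("\nFisher tests (pCR vs RD):\n")
  for (nm in names(x$fisher))
    cat(sprintf("  %-12s p = %.4f  (table %s)\n", nm,
                x$fisher[[nm]]$p_value,
                paste(x$fisher[[nm]]$table, collapse = "/")))
  cat("\nSpearman correlations:\n")
  cc <- x$correlations
  cc$rho <- round(cc$rho, 2); cc$p_value <- round(cc$p_value, 4)
  print(cc, row.names = FALSE)
  for (tp in names(x$survival)) {
    b <- x$survival[[tp]]
    cat(sprintf("\nDDFS at %s MRI (n = %d, %d excluded):\n", tp, b$n,
                b$n_excluded))
    if (!is.null(b$log_rank))
      cat(sprintf("  log-rank chi2 = %.2f (df %d), p = %.4f\n",
                  b$log_rank$chi2, b$log_rank$df, b$log_rank$p_value))
    if (!is.null(b$cox_rd_other_vs_fast)) {
      cr <- b$cox_rd_other_vs_fast
      cat(sprintf("  HR (RD other vs fast washout) = %.3f (95%% CI %.3f-%.3f), p = %.4f\n",
                  cr$hr, cr$ci95[1], cr$ci95[2], cr$p_value))
    }
    fy <- b$five_year
    cat("  five-year DDFS: ",
        paste(sprintf("%s %.1f%%", names(fy), 100 * fy), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Recompute the bundled reference analyses
#'
#' Re-runs Fisher's exact test on the six bundled 2x2 tables and the
#' diagnostic-performance computation on the six reconstructed confusion
#' matrices, and compares each result with the reported value at its
#' printed rounding. Deterministic: two runs give identical output.
#'
#' @return A data frame with columns `analysis`, `quantity`, `computed`,
#'   `reported`, `agrees`.
#' @export
reproduce_reference <- function() {
  fx <- reference_fixtures()
  rows <- list()
  for (nm in names(fx$contingency)) {
    tab <- fx$contingency[[nm]]
    p <- fisher_exact_two_sided(tab["a"], tab["b"], tab["c"], tab["d"])
    rep_p <- fx$reported$fisher_p[[nm]]
    digits <- max(nchar(sub(".*\\.", "", format(rep_p, scientific = FALSE))), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = nm, quantity = "fisher_p", computed = p, reported = rep_p,
      agrees = round(p, digits) == rep_p)
  }
  perf_rep <- fx$reported$performance
  for (nm in names(fx$confusion)) {
    cm <- fx$confusion[[nm]]
    perf <- diagnostic_performance(cm["tp"], cm["fp"], cm["fn"], cm["tn"])
    rr <- perf_rep[perf_rep$row == nm, ]
    for (q in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = nm, quantity = q, computed = perf[[q]],
        reported = rr[[q]], agrees = round(perf[[q]], 1) == rr[[q]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
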