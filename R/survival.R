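#' Build distant disease-free survival records from a cohort table
#'
#' DDFS is the time from the start of preoperative chemotherapy to the
#' occurrence of distant metastasis; patients without an event are
#' right-censored at their most recent follow-up. The grouping variable
#' is the three-group imaging split ([survival_group()]) at the chosen
#' timepoint. Records with missing or non-positive follow-up time, or
#' with no assignable group, are dropped with a logged count.
#'
#' @param cohort A validated cohort data frame (see [read_cohort()]).
#' @param timepoint `"mid"` or `"post"`: which MRI defines the group.
#' @return A data frame with columns `patient_id`, `time` (years),
#'   `event` (logical) and `group` (factor), plus attribute
#'   `"n_excluded"`.
#' @export
build_ddfs <- function(cohort, timepoint = c("post", "mid")) {
  timepoint <- match.arg(timepoint)
  size <- cohort[[paste0("size_", timepoint)]]
  curve <- cohort[[paste0("curve_", timepoint)]]
  ok_size <- !is.na(size) & size >= 0
  grp <- rep(factor(NA, levels = c("cr_mri", "rd_fast_washout", "rd_other")),
             nrow(cohort))
  grp[ok_size] <- survival_group(size[ok_size], curve[ok_size])
  keep <- !is.na(cohort$ddfs_years) & cohort$ddfs_years > 0 &
    !is.na(cohort$ddfs_event) & !is.na(grp)
  n_excl <- sum(!keep)
  if (any(!is.na(cohort$ddfs_years) & cohort$ddfs_years <= 0))
    warning(sum(!is.na(cohort$ddfs_years) & cohort$ddfs_years <= 0),
            " record(s) rejected: non-positive follow-up time")
  out <- data.frame(
    patient_id = cohort$patient_id[keep],
    time = cohort$ddfs_years[keep],
    event = cohort$ddfs_event[keep],
    group = droplevels(grp[keep])
  )
  attr(out, "n_excluded") <- n_excl
  out
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator; censoring at an event time is processed
#' after the events at that time (the standard convention).
#'
#' @param time Follow-up times (> 0).
#' @param event Logical event indicators.
#' @return An object of class `km_curve`: a list with `event_times`
#'   (distinct times with at least one event), `survival` (S(t) just
#'   after each event time), `at_risk`, `n_events`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  has_event <- fit$n.event > 0
  structure(list(
    event_times = fit$time[has_event],
    survival = fit$surv[has_event],
    at_risk = fit$n.risk[has_event],
    n_events = fit$n.event[has_event],
    n = length(time),
    fit = fit
  ), class = "km_curve")
}

#' Survival probability at a horizon
#'
#' Reads the Kaplan-Meier curve at the largest event time not exceeding
#' the horizon (so a curve with no event before the horizon yields 1).
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param years Horizon in years (default 5).
#' @return S(years).
#' @export
survival_at <- function(km, years = 5) {
  stopifnot(inherits(km, "km_curve"))
  idx <- which(km$event_times <= years)
  if (!length(idx)) return(1)
  km$survival[max(idx)]
}

#' Log-rank test across survival groups
#'
#' Standard K-sample log-rank statistic referred to a chi-square
#' distribution with K - 1 degrees of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list with `chi2`, `df` and `p_value`.
#' @export
log_rank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L)
    stop("log-rank test needs at least 2 non-empty groups")
  if (any(table(group) == 0L)) stop("a group has zero records")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for a group contrast
#'
#' Partial-likelihood estimation with the Efron approximation for tied
#' event times (Breslow available via `ties`). The hazard ratio is for
#' the second factor level relative to the first, with a Wald 95\%
#' confidence interval `exp(log HR +/- 1.96 SE)`. A monotone partial
#' likelihood (complete separation, e.g. all events in one group) is
#' reported as non-convergence: the estimate diverges and the Wald
#' interval is meaningless.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level factor (or coercible).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_result`: list with `log_hr`, `hr`,
#'   `se`, `ci95` (length-2), `p_value` (Wald), `converged`,
#'   `events_by_group` and `n_by_group`.
#' @export
cox_ph <- function(time, event, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("cox_ph expects exactly 2 group levels; got ", nlevels(group))
  if (sum(event) < 1L) stop("no events in the data")
  ev_by <- tapply(as.logical(event), group, sum)
  n_by <- table(group)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 100
  if (!converged)
    warning("monotone partial likelihood (complete separation); ",
            "hazard ratio estimate did not converge")
  structure(list(
    log_hr = beta,
    hr = exp(beta),
    se = se,
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged,
    events_by_group = ev_by,
    n_by_group = n_by,
    fit = fit
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards group contrast\n")
  cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f), Wald p = %.4f%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p_value,
              if (!x$converged) "  [did not converge]" else ""))
  ev <- paste(sprintf("%s: %d/%d", names(x$n_by_group),
                      as.integer(x$events_by_group),
                      as.integer(x$n_by_group)), collapse = ", ")
  cat("  events/n  ", ev, "\n")
  invisible(x)
}

#' Plot distant disease-free survival curves by group
#'
#' Base-graphics Kaplan-Meier plot, one curve per group.
#'
#' @param time,event,group As in [log_rank()].
#' @param ... Passed to [graphics::plot()].
#' @return The [survival::survfit] object, invisibly.
#' @export
plot_ddfs <- function(time, event, group, ...) {
  group <- droplevels(as.factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  graphics::plot(fit, col = seq_len(nlevels(group)), lwd = 2,
                 xlab = "Years from start of chemotherapy",
                 ylab = "Distant disease-free survival", ...)
  graphics::legend("bottomleft", legend = levels(group),
                   col = seq_len(nlevels(group)), lwd = 2, bty = "n")
  invisible(fit)
}
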