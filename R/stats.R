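#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the sum-of-small-probabilities rule: the sum,
#' over all tables with the observed margins, of hypergeometric
#' probabilities not exceeding that of the observed table (with a
#' relative tolerance of 1e-7 guarding floating-point ties). The table is
#' laid out with rows as the imaging stratum and columns as the
#' pathological outcome:
#' \preformatted{    a  b
#'     c  d}
#'
#' @param a,b,c,d Non-negative integer counts. Alternatively `a` may be
#'   a 2x2 matrix and the remaining arguments omitted.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(2, 12, 24, 19)  # ~0.0118
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2L, 2L)
  }
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (sum(m) == 0L) stop("table is empty")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margins (an all-zero row or column); p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Diagnostic performance of a binary predictor
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' overall accuracy, in percent, from a confusion matrix of a binary
#' imaging predictor against pathological truth. A metric whose
#' denominator is zero is undefined and returned as `NA` with a warning.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives).
#' @return A data frame with one row and columns `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percent) and `n`.
#' @examples
#' diagnostic_performance(23, 7, 5, 24)
#' @export
diagnostic_performance <- function(tp, fp, fn, tn) {
  cnt <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0L) stop("confusion matrix is empty")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  data.frame(
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    ppv = safe(tp, tp + fp, "PPV"),
    npv = safe(tn, tn + fn, "NPV"),
    accuracy = 100 * (tp + tn) / n,
    n = n
  )
}

# Confusion matrix of a logical prediction against logical truth,
# counting and reporting exclusions (NA in either vector).
confusion_counts <- function(predicted, truth) {
  keep <- !is.na(predicted) & !is.na(truth)
  p <- predicted[keep]; t <- truth[keep]
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t), n_excluded = sum(!keep))
}

#' Spearman rank correlation with large-sample p-value
#'
#' The rank correlation is the product-moment correlation of mid-ranks
#' (average ranks for ties); the p-value uses the large-sample t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped; at least 3 complete pairs required).
#' @return A list with `rho`, `p_value` and `n` (complete pairs).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant sequence: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

# Agreement category for an intraclass correlation coefficient.
# Boundaries at 0.50 and 0.75 belong to "moderate", 0.90 to "good";
# only values strictly above 0.90 are "excellent".
icc_category <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, !is.na(icc))
  if (icc < 0.50) "poor"
  else if (icc <= 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Inter-rater agreement by intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation (ICC(2,1)) from the two-way ANOVA decomposition of a
#' subjects x raters rating matrix, with the conventional agreement
#' categories: poor (< 0.50), moderate (0.50--0.75), good (0.75--0.90)
#' and excellent (> 0.90).
#'
#' @param ratings_r1,ratings_r2 Numeric rating vectors of the two raters
#'   on the same subjects (equal length >= 3), or `ratings_r1` may be a
#'   subjects x raters matrix with >= 2 columns.
#' @return A list with `icc`, `category` and the ANOVA mean squares
#'   (`msr`, `msc`, `mse`).
#' @export
icc_agreement <- function(ratings_r1, ratings_r2 = NULL) {
  if (is.matrix(ratings_r1)) {
    m <- ratings_r1
  } else {
    if (is.null(ratings_r2)) stop("two rating vectors (or a matrix) required")
    if (length(ratings_r1) != length(ratings_r2))
      stop("rating vectors must have equal length")
    m <- cbind(ratings_r1, ratings_r2)
  }
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)        # subjects
  ssc <- n * sum((col_means - grand)^2)        # raters
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 1e-12 && mse <= 1e-12) {
    warning("no between-subject variance: ICC undefined")
    return(list(icc = NA_real_, category = NA_character_,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, category = icc_category(icc), msr = msr, msc = msc, mse = mse)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance, two-sided two-sample t-test. Welch's unequal-variance
#' form is available with `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors (missing values dropped; >= 2 values each).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A list with `t`, `p_value`, `df` and the group means.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero pooled variance with equal means: t undefined")
      return(list(t = NA_real_, p_value = NA_real_, df = NA_real_,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    warning("zero pooled variance: t undefined")
    return(list(t = NA_real_, p_value = NA_real_, df = NA_real_,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y))
}
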