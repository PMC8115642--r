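test_that("Fisher two-sided p matches hand-enumerable tables", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
})

test_that("Fisher p agrees with full enumeration for random small tables", {
  set.seed(51)
  for (i in 1:60) {
    cnt <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    if (any(rowSums(matrix(cnt, 2)) == 0) || any(colSums(matrix(cnt, 2)) == 0))
      next
    expect_equal(fisher_exact_two_sided(cnt[1], cnt[2], cnt[3], cnt[4]),
                 oracle_fisher2x2(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9,
                 info = paste(cnt, collapse = ","))
  }
})

test_that("Fisher p is invariant under row swap, column swap and transpose", {
  set.seed(52)
  for (i in 1:20) {
    x <- sample(0:12, 4, replace = TRUE)
    if (any(rowSums(matrix(x, 2)) == 0) || any(colSums(matrix(x, 2)) == 0))
      next
    p0 <- fisher_exact_two_sided(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_two_sided(x[3], x[4], x[1], x[2]), p0)  # rows
    expect_equal(fisher_exact_two_sided(x[2], x[1], x[4], x[3]), p0)  # cols
    expect_equal(fisher_exact_two_sided(x[1], x[3], x[2], x[4]), p0)  # transpose
  }
})

test_that("degenerate margins yield p = 1 with a warning", {
  expect_warning(p <- fisher_exact_two_sided(0, 0, 3, 5), "degenerate")
  expect_equal(p, 1)
})

test_that("diagnostic performance handles perfect and degenerate classifiers", {
  perfect <- diagnostic_performance(1, 0, 0, 1)
  expect_equal(unlist(perfect[1:5]), c(sensitivity = 100, specificity = 100,
                                       ppv = 100, npv = 100, accuracy = 100))
  expect_warning(deg <- diagnostic_performance(0, 0, 5, 5), "PPV undefined")
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 100)
  expect_true(is.na(deg$ppv))
})

test_that("diagnostic metrics satisfy the count-space accuracy identity", {
  set.seed(53)
  for (i in 1:30) {
    cm <- sample(1:30, 4, replace = TRUE)
    perf <- diagnostic_performance(cm[1], cm[2], cm[3], cm[4])
    n <- sum(cm)
    expect_equal(perf$accuracy * n,
                 perf$sensitivity * (cm[1] + cm[3]) +
                 perf$specificity * (cm[4] + cm[2]),
                 tolerance = 1e-9)
  }
})

test_that("Spearman correlation equals rank-then-Pearson with mid-ranks", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_rho(1:4, c(4, 3, 2, 1))$rho, -1)
  set.seed(54)
  for (i in 1:20) {
    x <- sample(1:6, 30, replace = TRUE)   # heavy ties
    y <- x + sample(0:3, 30, replace = TRUE)
    res <- spearman_rho(x, y)
    expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    # large-sample t approximation
    r <- res$rho
    tstat <- r * sqrt((30 - 2) / (1 - r^2))
    expect_equal(res$p_value, 2 * pt(-abs(tstat), 28), tolerance = 1e-9)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(55)
  x <- rnorm(40); y <- rnorm(40)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, y^3)$rho, r0)
})

test_that("constant sequences leave Spearman undefined", {
  expect_warning(res <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("ICC(2,1) is 1 for identical ratings and follows the ANOVA form", {
  x <- c(1, 5, 9, 3, 7)
  res <- icc_agreement(x, x)
  expect_equal(res$icc, 1)
  expect_equal(res$category, "excellent")
})

test_that("ICC recovers the analytic value for known variance components", {
  set.seed(56)
  n <- 600
  sigma_s <- 3; sigma_r <- 0.8; sigma_e <- 1.2
  subj <- rnorm(n, 0, sigma_s)
  rater_shift <- c(-1, 1) * sigma_r  # fixed draw of the rater effect
  r1 <- subj + rater_shift[1] + rnorm(n, 0, sigma_e)
  r2 <- subj + rater_shift[2] + rnorm(n, 0, sigma_e)
  target <- sigma_s^2 / (sigma_s^2 + sigma_r^2 + sigma_e^2)
  res <- icc_agreement(r1, r2)
  expect_lt(abs(res$icc - target), 0.06)
})

test_that("ICC agreement categories use the printed boundaries", {
  expect_equal(washoutMRI:::icc_category(0.49), "poor")
  expect_equal(washoutMRI:::icc_category(0.50), "moderate")
  expect_equal(washoutMRI:::icc_category(0.60), "moderate")
  expect_equal(washoutMRI:::icc_category(0.75), "moderate")
  expect_equal(washoutMRI:::icc_category(0.76), "good")
  expect_equal(washoutMRI:::icc_category(0.90), "good")
  expect_equal(washoutMRI:::icc_category(0.905), "excellent")
})

test_that("no between-subject variance leaves ICC undefined", {
  expect_warning(res <- icc_agreement(rep(2, 5), rep(2, 5)), "undefined")
  expect_true(is.na(res$icc))
})

test_that("pooled t-test handles identical and degenerate samples", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_warning(deg <- two_sample_t(c(0, 0), c(1, 1)), "zero pooled variance")
  expect_true(is.na(deg$t))
})

test_that("pooled t-test holds its nominal type-I error under the null", {
  set.seed(57)
  reps <- 4000
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(12); y <- rnorm(12)
    if (two_sample_t(x, y)$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.05), 0.015)
})
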