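test_that("phantom generation is bit-reproducible per seed and varies across seeds", {
  base <- function(seed) phantom_spec(dim = c(14, 14, 10),
                                      lesion = list(center = c(7, 7, 5), radius = 5),
                                      noise_sd = 4, seed = seed)
  a <- simulate_phantom(base(1))
  b <- simulate_phantom(base(1))
  c2 <- simulate_phantom(base(2))
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$delay$data, b$delay$data)
  expect_false(identical(a$pre$data, c2$pre$data))
})

test_that("phantom ground truth is consistent with the noise-free ROI search", {
  spec <- phantom_spec(dim = c(18, 18, 12),
                       lesion = list(center = c(9, 9, 6), radius = 6),
                       subregions = list(list(center = c(9, 9, 6), radius = 5,
                                              si_pre = 120, ratio = 300, wi = 30)),
                       noise_sd = 0)
  ph <- simulate_phantom(spec)
  expect_equal(ph$truth$wi_max_planted, 30)
  expect_true(ph$truth$top_region_recoverable)
  lk <- lesion_max_wi(ph$pre, ph$early, ph$delay, ph$mask)
  expect_equal(lk$wi, 30, tolerance = 1e-9)
})

test_that("a subregion too small for the disc is flagged not recoverable", {
  spec <- phantom_spec(dim = c(18, 18, 12),
                       lesion = list(center = c(9, 9, 6), radius = 6),
                       subregions = list(list(center = c(9, 9, 6), radius = 1.2,
                                              si_pre = 120, ratio = 300, wi = 40)),
                       noise_sd = 0)
  ph <- simulate_phantom(spec)
  expect_false(ph$truth$top_region_recoverable)
  expect_lt(ph$truth$wi_max_recoverable, 40)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(subregions = list(
    list(center = c(30, 30, 30), radius = 3, si_pre = 100, ratio = 250, wi = 20))),
    "outside the lesion")
  expect_error(phantom_spec(
    lesion = list(center = c(16, 16, 10), radius = 12),
    subregions = list(
      list(center = c(13, 16, 10), radius = 3, si_pre = 100, ratio = 250, wi = 20),
      list(center = c(17, 16, 10), radius = 3, si_pre = 100, ratio = 250, wi = 5))),
    "disjoint")
})

test_that("cohort simulation is reproducible and schema-valid", {
  a <- simulate_cohort(cohort_spec(n = 200, seed = 71))
  b <- simulate_cohort(cohort_spec(n = 200, seed = 71))
  c2 <- simulate_cohort(cohort_spec(n = 200, seed = 72))
  expect_identical(a, b)
  expect_false(identical(a$wi_mid, c2$wi_mid))
  expect_silent(validate_cohort(a))
})

test_that("cohort marginals converge to the specified class frequencies", {
  co <- simulate_cohort(cohort_spec(n = 20000, seed = 73))
  freq <- as.vector(table(factor(co$rcb_class, levels = 0:3))) / nrow(co)
  expect_true(all(abs(freq - c(0.324, 0.230, 0.365, 0.081)) < 0.015))
  expect_equal(co$pcr, co$rcb_class == 0)
  expect_true(all((co$rcb_index == 0) == (co$rcb_class == 0)))
})

test_that("cohort kinetics respect the size-zero and curve-type invariants", {
  co <- simulate_cohort(cohort_spec(n = 2000, seed = 74))
  for (tp in c("pre", "mid", "post")) {
    size <- co[[paste0("size_", tp)]]
    wi <- co[[paste0("wi_", tp)]]
    curve <- co[[paste0("curve_", tp)]]
    expect_true(all(is.na(wi[size == 0])))
    expect_true(all(curve[size == 0] == "none"))
    expect_true(all(curve[size > 0] %in% c("fast_washout", "other")))
    # the fast-washout label implies the inclusive WI threshold
    expect_true(all(wi[size > 0 & curve == "fast_washout"] >= 10))
  }
  # group separation the generator is meant to plant: pCR WI lower at mid
  expect_lt(mean(co$wi_mid[co$pcr], na.rm = TRUE),
            mean(co$wi_mid[!co$pcr], na.rm = TRUE))
})

test_that("cohort survival recovers the planted hazard ratio at large n", {
  co <- simulate_cohort(cohort_spec(n = 2000, seed = 75))
  dd <- build_ddfs(co, timepoint = "post")
  rd <- dd[dd$group != "cr_mri", ]
  rd$group <- droplevels(rd$group)
  f <- cox_ph(rd$time, rd$event, rd$group)
  expect_lt(abs(f$log_hr - log(0.10)), 3 * f$se)
})

test_that("the two-group exponential generator is seeded and censoring-aware", {
  a <- simulate_ddfs_groups(n = 300, hr = 0.2, seed = 76)
  b <- simulate_ddfs_groups(n = 300, hr = 0.2, seed = 76)
  expect_identical(a, b)
  # with no censoring window above the horizon all subjects with events
  expect_true(mean(a$event[a$group == "a"]) > mean(a$event[a$group == "b"]))
})

test_that("reference fixtures carry internally consistent counts", {
  fx <- reference_fixtures()
  expect_equal(fx$contingency$curve_mid, c(a = 2, b = 12, c = 24, d = 19))
  expect_equal(fx$contingency$size_post, c(a = 28, b = 27, c = 1, d = 13))
  expect_equal(fx$contingency$lesion_type, c(a = 23, b = 32, c = 6, d = 13))
  # every reconstructed confusion matrix reproduces its five percentages
  perf <- fx$reported$performance
  for (nm in names(fx$confusion)) {
    cm <- fx$confusion[[nm]]
    got <- diagnostic_performance(cm["tp"], cm["fp"], cm["fn"], cm["tn"])
    want <- perf[perf$row == nm, ]
    expect_equal(round(got$sensitivity, 1), want$sensitivity, info = nm)
    expect_equal(round(got$specificity, 1), want$specificity, info = nm)
    expect_equal(round(got$ppv, 1), want$ppv, info = nm)
    expect_equal(round(got$npv, 1), want$npv, info = nm)
    expect_equal(round(got$accuracy, 1), want$accuracy, info = nm)
  }
})
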