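#' Bundled reference tables from the motivating neoadjuvant TNBC cohort
#'
#' Count tables reported for a retrospective cohort of 74
#' neoadjuvant-treated triple-negative breast cancer patients, bundled
#' so the statistical machinery can be exercised end-to-end without
#' patient data.
#'
#' `contingency` holds six 2x2 tables (rows = imaging stratum, columns =
#' pCR / residual disease, layout `c(a, b, c, d)`):
#' \itemize{
#'   \item `lesion_type`: mass vs other morphology at the baseline MRI;
#'   \item `size_pre`, `size_mid`, `size_post`: lesion size < 20 mm vs
#'     >= 20 mm at each timepoint;
#'   \item `curve_mid`, `curve_post`: fast-washout vs other curve type.
#' }
#'
#' `confusion` holds one confusion matrix (`tp`, `fp`, `fn`, `tn`) per
#' diagnostic-performance row. These counts are *reconstructed*, not
#' observed: they were derived as the integer matrices that reproduce
#' all five reported percentages (sensitivity, specificity, PPV, NPV,
#' accuracy) of each row simultaneously, and the reconstruction is
#' re-verified arithmetically in the test suite. Row names encode
#' endpoint and predictor, e.g. `pcr_wi_mid` = predicting pCR by
#' "WI < 0 or size = 0" at the mid-treatment MRI, `rcb1_wi_post` =
#' predicting RCB class <= I at the post-treatment MRI,
#' `pcr_size_mid` = predicting pCR by "size = 0" alone.
#'
#' `reported` carries the values printed for the same analyses (Fisher
#' p-values to their printed rounding and performance percentages to one
#' decimal), for use by [reproduce_reference()].
#'
#' @return A list with components `contingency`, `confusion`, `reported`.
#' @export
reference_fixtures <- function() {
  contingency <- list(
    lesion_type = c(a = 23, b = 32, c = 6, d = 13),
    size_pre    = c(a = 4,  b = 7,  c = 12, d = 25),
    size_mid    = c(a = 26, b = 23, c = 3,  d = 10),
    size_post   = c(a = 28, b = 27, c = 1,  d = 13),
    curve_mid   = c(a = 2,  b = 12, c = 24, d = 19),
    curve_post  = c(a = 0,  b = 21, c = 13, d = 17)
  )
  confusion <- list(
    rcb1_wi_mid   = c(tp = 25, fp = 5,  fn = 10, tn = 19),
    rcb1_wi_post  = c(tp = 34, fp = 3,  fn = 4,  tn = 27),
    pcr_wi_mid    = c(tp = 23, fp = 7,  fn = 5,  tn = 24),
    pcr_wi_post   = c(tp = 25, fp = 12, fn = 3,  tn = 28),
    pcr_size_mid  = c(tp = 2,  fp = 1,  fn = 27, tn = 32),
    pcr_size_post = c(tp = 15, fp = 2,  fn = 14, tn = 38)
  )
  reported <- list(
    fisher_p = c(lesion_type = 0.5870, size_pre = 1.0000, size_mid = 0.0670,
                 size_post = 0.0049, curve_mid = 0.0118, curve_post = 0.0003),
    performance = data.frame(
      row = names(confusion),
      sensitivity = c(71.4, 89.5, 82.1, 89.3, 6.9, 51.7),
      specificity = c(79.2, 90.0, 77.4, 70.0, 97.0, 95.0),
      ppv = c(83.3, 91.9, 76.7, 67.6, 66.7, 88.2),
      npv = c(65.5, 87.1, 82.8, 90.3, 54.2, 73.1),
      accuracy = c(74.6, 89.7, 79.7, 77.9, 54.8, 76.8),
      stringsAsFactors = FALSE
    )
  )
  list(contingency = contingency, confusion = confusion, reported = reported)
}
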