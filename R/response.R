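#' RECIST response category from longest diameters
#'
#' Categorises the change between a baseline and a follow-up longest
#' diameter: complete response (`CR`) when no enhancing lesion remains
#' (follow-up size 0); progressive disease (`PD`) when the diameter
#' increased by at least 20\%; partial response (`PR`) when it decreased
#' by at least 30\%; stable disease (`SD`) otherwise. Both change
#' thresholds are inclusive, and PD is tested before PR so the
#' categorisation is deterministic.
#'
#' @param baseline_size,followup_size Longest diameters in mm (vectors,
#'   recycled). `baseline_size` must be positive.
#' @return Factor with levels `CR`, `PR`, `SD`, `PD`.
#' @examples
#' recist_category(30, c(0, 21, 36, 25))  # CR PR PD SD
#' @export
recist_category <- function(baseline_size, followup_size) {
  if (anyNA(baseline_size) || any(baseline_size <= 0))
    stop_classed("washout_invalid_baseline",
                 "baseline size must be positive for RECIST categorisation")
  if (anyNA(followup_size) || any(followup_size < 0))
    stop("follow-up size must be non-negative")
  n <- max(length(baseline_size), length(followup_size))
  b <- rep_len(baseline_size, n)
  f <- rep_len(followup_size, n)
  change <- (f - b) / b
  out <- ifelse(f == 0, "CR",
         ifelse(change >= 0.20, "PD",
         ifelse(-change >= 0.30, "PR", "SD")))
  factor(out, levels = c("CR", "PR", "SD", "PD"))
}

#' Imaging predictor of pathological response: negative WI or vanished lesion
#'
#' The combined imaging rule for predicting pathological response (pCR,
#' or minimal residual cancer burden): positive when the lesion has
#' disappeared (`size_mm == 0`) or its maximal washout index is strictly
#' negative (no washout at all in the delayed phase).
#'
#' @param size_mm Lesion longest diameter in mm (0 = no enhancing lesion).
#' @param wi Maximal washout index in percent; may be `NA` when the
#'   lesion was not kinetically evaluable.
#' @return Logical vector; `NA` where a residual lesion has no measured
#'   WI (not evaluable, mirrored by per-analysis exclusion counts).
#' @examples
#' predict_pathresponse(c(0, 12, 12), c(NA, -5, 0))  # TRUE TRUE FALSE
#' @export
predict_pathresponse <- function(size_mm, wi) {
  n <- max(length(size_mm), length(wi))
  size_mm <- rep_len(size_mm, n)
  wi <- rep_len(wi, n)
  if (anyNA(size_mm) || any(size_mm < 0))
    stop("size_mm must be non-negative and non-missing")
  out <- size_mm == 0 | (!is.na(wi) & wi < 0)
  out[size_mm > 0 & is.na(wi)] <- NA
  out
}

#' Imaging predictor of pathological response: vanished lesion only
#'
#' @param size_mm Lesion longest diameter in mm.
#' @return Logical vector, `TRUE` iff `size_mm == 0`.
#' @export
predict_by_size <- function(size_mm) {
  if (anyNA(size_mm) || any(size_mm < 0))
    stop("size_mm must be non-negative and non-missing")
  size_mm == 0
}

#' Survival group from one timepoint observation
#'
#' Assigns the three-group split used for distant disease-free survival:
#' radiological complete response (`cr_mri`, no enhancing lesion),
#' residual lesion with a fast-washout curve type (`rd_fast_washout`),
#' or residual lesion with any other curve type (`rd_other`). "Residual"
#' here means residual enhancing lesion on MRI, since a curve type only
#' exists for enhancing lesions.
#'
#' @param size_mm Lesion longest diameter in mm.
#' @param curve_class Character vector (`"fast_washout"`, `"other"`,
#'   `"none"`, or `NA` when not evaluable).
#' @return Factor with levels `cr_mri`, `rd_fast_washout`, `rd_other`;
#'   `NA` where a residual lesion has no curve class.
#' @export
survival_group <- function(size_mm, curve_class) {
  n <- max(length(size_mm), length(curve_class))
  size_mm <- rep_len(size_mm, n)
  curve_class <- as.character(rep_len(curve_class, n))
  if (anyNA(size_mm) || any(size_mm < 0))
    stop("size_mm must be non-negative and non-missing")
  out <- rep(NA_character_, n)
  out[size_mm == 0] <- "cr_mri"
  res <- size_mm > 0
  out[res & !is.na(curve_class) & curve_class == "fast_washout"] <- "rd_fast_washout"
  out[res & !is.na(curve_class) & curve_class == "other"] <- "rd_other"
  factor(out, levels = c("cr_mri", "rd_fast_washout", "rd_other"))
}

#' Stratify lesion size at a cut-off
#'
#' @param size_mm Sizes in mm.
#' @param cut_mm Cut-off (default 20 mm); strata are `"<cut"` (strict)
#'   and `">=cut"`.
#' @return Factor with levels `"<cut"`, `">=cut"`.
#' @export
size_stratum <- function(size_mm, cut_mm = 20) {
  factor(ifelse(size_mm < cut_mm, "<cut", ">=cut"), levels = c("<cut", ">=cut"))
}
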