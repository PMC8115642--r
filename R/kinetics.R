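#' Kinetic curve-type thresholds
#'
#' The fast-washout curve type requires an initial enhancement ratio
#' strictly above `enhancement_min` (percent of the pre-contrast signal)
#' together with a washout index of at least `washout_min` percent. The
#' defaults are the conventional operating point used for neoadjuvant
#' breast DCE-MRI; both are exposed so that sensitivity analyses can move
#' them without touching the classification code.
#'
#' @param enhancement_min Minimum initial enhancement ratio in percent;
#'   the fast-washout condition is strict (`ratio > enhancement_min`).
#'   Default 200.
#' @param washout_min Minimum washout index in percent; the condition is
#'   inclusive (`wi >= washout_min`). Default 10.
#' @return A list with components `enhancement_min` and `washout_min`.
#' @examples
#' kinetic_thresholds()
#' kinetic_thresholds(enhancement_min = 180)
#' @export
kinetic_thresholds <- function(enhancement_min = 200, washout_min = 10) {
  stopifnot(is.numeric(enhancement_min), length(enhancement_min) == 1L,
            enhancement_min > 0,
            is.numeric(washout_min), length(washout_min) == 1L)
  list(enhancement_min = enhancement_min, washout_min = washout_min)
}

# Shared validation of a three-phase signal triplet. SI_pre must be
# strictly positive (it is a divisor); post-contrast signals only
# non-negative. Vectorised; raises a classed error so callers can skip
# bad ROIs selectively.
validate_kinetic_sample <- function(si_pre, si_early, si_delay = NULL) {
  if (!is.numeric(si_pre) || !is.numeric(si_early))
    stop_invalid_sample("signal intensities must be numeric")
  if (anyNA(si_pre) || any(si_pre <= 0))
    stop_invalid_sample("SI_pre must be strictly positive (unusable pre-contrast signal)")
  if (anyNA(si_early) || any(si_early < 0))
    stop_invalid_sample("SI_early must be non-negative")
  if (!is.null(si_delay)) {
    if (!is.numeric(si_delay) || anyNA(si_delay) || any(si_delay < 0))
      stop_invalid_sample("SI_delay must be non-negative")
  }
  invisible(TRUE)
}

stop_invalid_sample <- function(msg) {
  stop(structure(class = c("washout_invalid_sample", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Washout index of a three-phase kinetic sample
#'
#' The washout index quantifies the strength of contrast washout between
#' the early (1--2 min) and delayed (5--6 min) post-contrast phases,
#' normalised by the pre-contrast signal:
#' \deqn{WI = (SI_{early} - SI_{delay}) / SI_{pre} \times 100\%}
#' Positive values indicate signal loss in the delayed phase (washout);
#' negative values indicate persistent enhancement and are legal results,
#' not errors.
#'
#' @param si_pre,si_early,si_delay Numeric vectors of ROI signal
#'   intensities on the pre-contrast, early-phase and delayed-phase
#'   acquisitions (arbitrary units, recycled to a common length).
#'   `si_pre` must be strictly positive.
#' @return Numeric vector of washout indices in percent.
#' @examples
#' washout_index(100, 250, 230)  # 20
#' washout_index(100, 150, 180)  # -30, persistent enhancement
#' @seealso [enhancement_ratio()], [classify_curve()]
#' @export
washout_index <- function(si_pre, si_early, si_delay) {
  validate_kinetic_sample(si_pre, si_early, si_delay)
  (si_early - si_delay) / si_pre * 100
}

#' Initial enhancement ratio
#'
#' Early-phase signal relative to the pre-contrast signal, in percent:
#' `SI_early / SI_pre * 100`. A value of 100 means no enhancement.
#'
#' @inheritParams washout_index
#' @return Numeric vector of enhancement ratios in percent.
#' @examples
#' enhancement_ratio(100, 250)  # 250
#' @export
enhancement_ratio <- function(si_pre, si_early) {
  validate_kinetic_sample(si_pre, si_early)
  si_early / si_pre * 100
}

#' Classify the kinetic curve type of a three-phase sample
#'
#' A sample is a fast-washout curve type when the initial enhancement
#' ratio is strictly greater than the enhancement threshold (default
#' 200\%) and the washout index is at least the washout threshold
#' (default 10\%, inclusive). Every other combination -- including a
#' ratio of exactly 200\% -- is classified `"other"`.
#'
#' @inheritParams washout_index
#' @param thresholds Classification thresholds, see [kinetic_thresholds()].
#' @return A data frame with one row per sample and columns `wi`,
#'   `enhancement_ratio` (percent) and `curve_class` (factor with levels
#'   `"fast_washout"`, `"other"`).
#' @examples
#' classify_curve(100, 250, 230)  # fast_washout (ratio 250, WI 20)
#' classify_curve(100, 200, 150)  # other: ratio exactly 200 fails ">"
#' @export
classify_curve <- function(si_pre, si_early, si_delay,
                           thresholds = kinetic_thresholds()) {
  wi <- washout_index(si_pre, si_early, si_delay)
  ratio <- enhancement_ratio(si_pre, si_early)
  fast <- ratio > thresholds$enhancement_min & wi >= thresholds$washout_min
  data.frame(
    wi = wi,
    enhancement_ratio = ratio,
    curve_class = factor(ifelse(fast, "fast_washout", "other"),
                         levels = curve_levels())
  )
}

# Factor levels used for curve-type columns throughout the package;
# "none" marks lesions with no measurable enhancement (size 0).
curve_levels <- function() c("fast_washout", "other", "none")

#' Read kinetic samples from a delimited table
#'
#' Reads a table with columns `id`, `si_pre`, `si_early`, `si_delay`
#' (comma-separated, header row) and classifies every row.
#'
#' @param path Path to a delimited text file.
#' @param thresholds See [kinetic_thresholds()].
#' @return The input table with `wi`, `enhancement_ratio` and
#'   `curve_class` columns appended.
#' @export
read_kinetic_samples <- function(path, thresholds = kinetic_thresholds()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "si_pre", "si_early", "si_delay")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("kinetic sample table is missing columns: ", paste(miss, collapse = ", "))
  cbind(tab, classify_curve(tab$si_pre, tab$si_early, tab$si_delay, thresholds))
}
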