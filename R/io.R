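#' Read a DCE phase volume from a NIfTI file
#'
#' @param path Path to a 3-D NIfTI file.
#' @param phase One of `"pre"`, `"early"`, `"delay"`.
#' @return A [phase_volume()].
#' @export
read_phase_volume <- function(path, phase = c("pre", "early", "delay")) {
  phase <- match.arg(phase)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path, " but found ",
         length(dim(arr)), " dimensions")
  phase_volume(arr, RNifti::pixdim(img)[1:3], phase)
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Voxels with value > 0.5 are lesion members.
#'
#' @param path Path to a 3-D NIfTI file.
#' @return A [lesion_mask()].
#' @export
read_lesion_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D mask in ", path)
  lesion_mask(arr > 0.5, RNifti::pixdim(img)[1:3])
}

#' Write a volume or mask as NIfTI
#'
#' @param x A [phase_volume()] or [lesion_mask()].
#' @param path Destination file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "phase_volume") || inherits(x, "lesion_mask"))
  dat <- x$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Required columns of a cohort table (one row per patient).
cohort_columns <- function() {
  c("patient_id", "lesion_type", "rcb_index", "rcb_class", "pcr", "pt_mm",
    "size_pre", "size_mid", "size_post",
    "wi_pre", "wi_mid", "wi_post",
    "curve_pre", "curve_mid", "curve_post",
    "ddfs_years", "ddfs_event")
}

#' Validate a cohort table
#'
#' Checks the column schema and basic value constraints of a per-patient
#' cohort table: `lesion_type` in mass/nme/mixed, `rcb_class` in 0..3,
#' non-negative sizes, curve classes in fast_washout/other/none (empty or
#' NA meaning not evaluable), positive follow-up times, and the
#' size-zero consistency rule (a lesion of size 0 has no kinetics).
#'
#' @param cohort A data frame.
#' @return The cohort, invisibly, with curve columns normalised to
#'   character and logical columns to logical.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss))
    stop("cohort table is missing required columns: ",
         paste(miss, collapse = ", "))
  for (cl in c("curve_pre", "curve_mid", "curve_post")) {
    v <- as.character(cohort[[cl]])
    v[!is.na(v) & v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% curve_levels()
    if (any(bad))
      stop("column ", cl, " contains invalid curve classes: ",
           paste(unique(v[bad]), collapse = ", "))
    cohort[[cl]] <- v
  }
  cohort$pcr <- as.logical(cohort$pcr)
  cohort$ddfs_event <- as.logical(cohort$ddfs_event)
  if (any(!is.na(cohort$ddfs_years) & cohort$ddfs_years <= 0))
    stop("ddfs_years must be positive")
  for (cl in c("size_pre", "size_mid", "size_post")) {
    if (any(!is.na(cohort[[cl]]) & cohort[[cl]] < 0))
      stop(cl, " must be non-negative")
  }
  bad_rcb <- !is.na(cohort$rcb_class) & !cohort$rcb_class %in% 0:3
  if (any(bad_rcb)) stop("rcb_class must be 0, 1, 2 or 3")
  invisible(cohort)
}

#' Read a cohort table from delimited text
#'
#' Comma-separated, UTF-8, header row; empty fields are missing values.
#' See [validate_cohort()] for the schema.
#'
#' @param path Path to the file.
#' @return A validated data frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_cohort(tab)
  tab
}

#' Write a cohort table as delimited text
#'
#' @param cohort A cohort data frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
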