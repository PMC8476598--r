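#' Slide image container
#'
#' An RGB raster with physical resolution and slide/patient identity. Pixels
#' are stored as an `h x w x 3` numeric array in `[0, 1]`; all coordinates in
#' the package are 0-based `(row, col)`.
#'
#' @param slide_id Slide identifier, unique within a cohort.
#' @param patient_id Patient identifier.
#' @param pixels `h x w x 3` numeric array with values in `[0, 1]`.
#' @param resolution_um_per_px Physical resolution, micrometres per pixel.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(slide_id, patient_id, pixels, resolution_um_per_px) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L, nzchar(slide_id),
            is.character(patient_id), length(patient_id) == 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L ||
      dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("'pixels' must be a non-empty h x w x 3 array")
  }
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      !is.finite(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("'resolution_um_per_px' must be a single positive number")
  }
  structure(
    list(slide_id = slide_id, patient_id = patient_id,
         pixels = pixels, resolution_um_per_px = resolution_um_per_px),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s (patient %s): %d x %d px at %g um/px\n",
              x$slide_id, x$patient_id, d[1], d[2], x$resolution_um_per_px))
  invisible(x)
}

#' Per-pixel class mask
#'
#' A binary raster congruent with its slide, naming one tissue class.
#' Recognised classes: tumor, dbm_short, dbm_long, short_like, long_like,
#' neutral, necrosis, stroma, artifact, background.
#'
#' @param slide_id Slide the mask belongs to.
#' @param class_name One of the recognised class names.
#' @param mask Logical matrix (same shape as the slide raster).
#' @return An object of class `class_mask`.
#' @export
class_mask <- function(slide_id, class_name, mask) {
  classes <- c("tumor", "dbm_short", "dbm_long", "short_like", "long_like",
               "neutral", "necrosis", "stroma", "artifact", "background")
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!class_name %in% classes) {
    stop("unknown mask class '", class_name, "'")
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("'mask' must be a logical matrix")
  }
  structure(list(slide_id = slide_id, class_name = class_name, mask = mask),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  cat(sprintf("<class_mask> %s/%s: %d x %d, %d positive px\n",
              x$slide_id, x$class_name, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "class_mask")) x$mask else x
}

check_congruent <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  if (!identical(dim(a), dim(b))) {
    stop("masks are not congruent: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

#' Percent area of one mask within another
#'
#' Digital-biomarker areas are reported as percent of total tumor area; this
#' is the shared primitive. `part` must be a subset of `whole`.
#'
#' @param part,whole Logical matrices or `class_mask` objects of equal shape.
#' @return `100 * |part| / |whole|`, in `[0, 100]`.
#' @export
area_percent <- function(part, whole) {
  check_congruent(part, whole)
  p <- as_mask_matrix(part); w <- as_mask_matrix(whole)
  if (any(p & !w)) stop("'part' is not a subset of 'whole'")
  n_whole <- sum(w)
  if (n_whole == 0L) {
    stop("undefined denominator: 'whole' mask is empty")
  }
  100 * sum(p) / n_whole
}

#' Outcome label for a patient
#'
#' PFI groups are the extremes of platinum response: PFI_S is a
#' platinum-free interval of at most 6 months, PFI_L at least 18 months.
#'
#' @param patient_id Patient identifier.
#' @param group `"PFI_S"` or `"PFI_L"`.
#' @param pfi_months Optional platinum-free interval in months; checked for
#'   consistency with the group when supplied.
#' @return An object of class `outcome_label`.
#' @export
outcome_label <- function(patient_id, group, pfi_months = NA_real_) {
  group <- match.arg(group, c("PFI_S", "PFI_L"))
  if (!is.na(pfi_months)) {
    if (pfi_months < 0) stop("'pfi_months' must be non-negative")
    if (group == "PFI_S" && pfi_months > 6) {
      stop("PFI_S requires pfi_months <= 6, got ", pfi_months)
    }
    if (group == "PFI_L" && pfi_months < 18) {
      stop("PFI_L requires pfi_months >= 18, got ", pfi_months)
    }
  }
  structure(list(patient_id = patient_id, group = group,
                 pfi_months = pfi_months),
            class = "outcome_label")
}
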