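#' Convert a physical field of view to a patch size in pixels
#'
#' Model context windows are specified physically (micrometres) and realised
#' as square pixel patches through the slide resolution. The scanner
#' resolutions of the motivating study (0.22 and 0.24 um/px) give a 200 um
#' field of view of 909 and 833 px respectively; the synthetic default of
#' 2.0 um/px gives 100 px.
#'
#' @param fov_um Field of view in micrometres (> 0).
#' @param resolution_um_per_px Slide resolution in micrometres per pixel (> 0).
#' @return Integer patch side length in pixels, `round(fov_um / resolution)`,
#'   never less than 1.
#' @examples
#' fov_to_pixels(200, 0.22)  # 909
#' fov_to_pixels(200, 2.0)   # 100
#' @export
fov_to_pixels <- function(fov_um, resolution_um_per_px) {
  if (!is.numeric(fov_um) || length(fov_um) != 1L || !is.finite(fov_um) ||
      fov_um <= 0) {
    stop("invalid geometry: 'fov_um' must be a single positive number")
  }
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      !is.finite(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("invalid geometry: 'resolution_um_per_px' must be a single positive number")
  }
  max(1L, as.integer(round(fov_um / resolution_um_per_px)))
}

#' Field-of-view descriptor
#'
#' Bundles the physical context window with its pixel realisation at a given
#' resolution.
#'
#' @param fov_um Field of view in micrometres.
#' @param resolution_um_per_px Resolution in micrometres per pixel.
#' @return An object of class `fov` with elements `fov_um`,
#'   `resolution_um_per_px` and `patch_px`.
#' @export
field_of_view <- function(fov_um, resolution_um_per_px) {
  structure(
    list(
      fov_um = fov_um,
      resolution_um_per_px = resolution_um_per_px,
      patch_px = fov_to_pixels(fov_um, resolution_um_per_px)
    ),
    class = "fov"
  )
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov> %g um at %g um/px = %d px\n",
              x$fov_um, x$resolution_um_per_px, x$patch_px))
  invisible(x)
}

#' Equivalent circular diameter of a pixel blob
#'
#' Size measure used for the minimum-focus rule on biomarker components:
#' the diameter of the circle with the same area, in micrometres.
#'
#' @param area_px Component area in pixels.
#' @param resolution_um_per_px Resolution in micrometres per pixel.
#' @return Diameter in micrometres, `2 * sqrt(area_px / pi) * resolution`.
#' @export
equivalent_diameter_um <- function(area_px, resolution_um_per_px) {
  2 * sqrt(area_px / pi) * resolution_um_per_px
}
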