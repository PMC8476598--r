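# Patch extraction and fast patch statistics.
#
# A field of view is realised as a square patch of `patch_px` pixels. For a
# 0-based center (r, c) and p2 = floor(patch_px / 2) the patch spans rows
# (r - p2) .. (r - p2 + patch_px - 1); parts outside the slide are
# zero-padded. Grid centers are anchored at p2 so a patch whose center is the
# first grid point is flush with the slide corner.

patch_half <- function(patch_px) as.integer(floor(patch_px / 2))

#' Candidate patch-grid centers for a raster
#'
#' 0-based centers of a regular square grid with the given stride, anchored
#' at `floor(patch_px/2)` so the first patch is flush with the top-left
#' corner.
#'
#' @param dim_hw Integer vector `(height, width)` of the raster.
#' @param patch_px Patch side length in pixels.
#' @param stride_px Grid step in pixels (>= 1).
#' @return A two-column integer matrix of 0-based `(row, col)` centers.
#' @export
patch_grid_centers <- function(dim_hw, patch_px, stride_px) {
  stopifnot(stride_px >= 1, patch_px >= 1)
  p2 <- patch_half(patch_px)
  rows <- as.integer(seq.int(p2, dim_hw[1] - 1L, by = stride_px))
  cols <- as.integer(seq.int(p2, dim_hw[2] - 1L, by = stride_px))
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Extract labeled patches whose centers fall inside a mask
#'
#' Realises field-of-view training context as square patches on a regular
#' grid. Patches that overhang the slide border are zero-padded so that area
#' accounting stays exact at slide edges. An empty mask yields an empty
#' result, not an error.
#'
#' @param slide A `slide_image`.
#' @param mask Logical matrix or `class_mask` congruent with the slide;
#'   only grid centers where the mask is `TRUE` are emitted.
#' @param patch_px Patch side length in pixels.
#' @param stride_px Grid stride in pixels.
#' @param label Optional label attached to every emitted patch.
#' @return A list with `patches` (list of `patch_px x patch_px x 3` arrays),
#'   `centers` (0-based `(row, col)` matrix) and `labels`.
#' @export
extract_patches <- function(slide, mask, patch_px, stride_px, label = NA) {
  m <- as_mask_matrix(mask)
  check_congruent(m, slide$pixels[, , 1])
  stopifnot(stride_px >= 1)
  centers <- patch_grid_centers(dim(m), patch_px, stride_px)
  keep <- m[cbind(centers[, 1] + 1L, centers[, 2] + 1L)]
  centers <- centers[keep, , drop = FALSE]
  patches <- lapply(seq_len(nrow(centers)), function(i) {
    extract_one_patch(slide$pixels, centers[i, 1], centers[i, 2], patch_px)
  })
  list(patches = patches, centers = centers,
       labels = rep(label, nrow(centers)))
}

extract_one_patch <- function(pixels, r0, c0, patch_px) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  p2 <- patch_half(patch_px)
  out <- array(0, dim = c(patch_px, patch_px, 3))
  rs <- r0 - p2 + 1L          # 1-based slide row of patch row 1
  cs <- c0 - p2 + 1L
  pr <- seq_len(patch_px); pc <- seq_len(patch_px)
  in_r <- pr[rs + pr - 1L >= 1L & rs + pr - 1L <= h]
  in_c <- pc[cs + pc - 1L >= 1L & cs + pc - 1L <= w]
  if (length(in_r) && length(in_c)) {
    out[in_r, in_c, ] <- pixels[rs + in_r - 1L, cs + in_c - 1L, , drop = FALSE]
  }
  out
}

# --- fast patch statistics via summed-area tables ------------------------

cumsum2 <- function(m) {
  cs <- apply(m, 2, cumsum)
  t(apply(cs, 1, cumsum))
}

integral_image <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 1L, w + 1L)
  out[-1L, -1L] <- cumsum2(m)
  out
}

# Luminance gradient magnitude |dx| + |dy|, zero on the trailing edge.
gradient_magnitude <- function(pixels) {
  lum <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  h <- nrow(lum); w <- ncol(lum)
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)
  if (w > 1) dx[, -w] <- abs(lum[, -1L] - lum[, -w])
  if (h > 1) dy[-h, ] <- abs(lum[-1L, ] - lum[-h, ])
  dx + dy
}

#' Precompute per-slide statistics for O(1) patch features
#'
#' Builds summed-area tables for each color channel and for the luminance
#' gradient magnitude so patch moments cost constant time per patch.
#'
#' @param slide A `slide_image`.
#' @return An opaque `slide_stats` object consumed by [patch_features()].
#' @export
slide_stats <- function(slide) {
  px <- slide$pixels
  gm <- gradient_magnitude(px)
  chans <- list(px[, , 1], px[, , 2], px[, , 3], gm)
  structure(
    list(
      dim = dim(px)[1:2],
      s1 = lapply(chans, integral_image),
      s2 = lapply(chans, function(m) integral_image(m * m))
    ),
    class = "slide_stats"
  )
}

#' Patch feature matrix at given centers
#'
#' Multi-scale color moments and texture energy: the mean and (population)
#' standard deviation of the red, green and blue channels and of the
#' luminance gradient magnitude, computed over three concentric windows --
#' the full patch (the field-of-view context) and center sub-windows of
#' half and quarter side (local detail, which keeps class boundaries sharp
#' when the context window straddles them). Windows are clipped to the
#' slide; border patches use their valid region. 24 features per patch.
#'
#' @param stats A `slide_stats` object.
#' @param centers 0-based `(row, col)` matrix of patch centers.
#' @param patch_px Patch side length in pixels.
#' @return Numeric matrix, one row per center; columns named
#'   `<chan>_<stat>_s<scale>` for chan in r, g, b, grad, stat in mean, sd
#'   and scale in 1 (full), 2 (half), 4 (quarter).
#' @export
patch_features <- function(stats, centers, patch_px) {
  stopifnot(inherits(stats, "slide_stats"))
  scales <- c(1L, 2L, 4L)
  if (nrow(centers) == 0L) {
    out <- matrix(numeric(0), 0, 8L * length(scales))
    colnames(out) <- feature_names()
    return(out)
  }
  out <- do.call(cbind, lapply(scales, function(s) {
    window_features(stats, centers, max(1L, patch_px %/% s))
  }))
  colnames(out) <- feature_names()
  out
}

window_features <- function(stats, centers, patch_px) {
  h <- stats$dim[1]; w <- stats$dim[2]
  p2 <- patch_half(patch_px)
  r1 <- pmax(1L, centers[, 1] + 1L - p2)
  r2 <- pmin(h, centers[, 1] + 1L - p2 + patch_px - 1L)
  c1 <- pmax(1L, centers[, 2] + 1L - p2)
  c2 <- pmin(w, centers[, 2] + 1L - p2 + patch_px - 1L)
  n <- (r2 - r1 + 1) * (c2 - c1 + 1)
  out <- matrix(0, nrow(centers), 8)
  for (k in seq_along(stats$s1)) {
    s1 <- window_sum(stats$s1[[k]], r1, r2, c1, c2)
    s2 <- window_sum(stats$s2[[k]], r1, r2, c1, c2)
    mu <- s1 / n
    out[, 2L * k - 1L] <- mu
    out[, 2L * k] <- sqrt(pmax(0, s2 / n - mu * mu))
  }
  out
}

feature_names <- function() {
  base <- c("r_mean", "r_sd", "g_mean", "g_sd", "b_mean", "b_sd",
            "grad_mean", "grad_sd")
  as.vector(vapply(c(1L, 2L, 4L),
                   function(s) paste0(base, "_s", s),
                   character(8)))
}

window_sum <- function(ii, r1, r2, c1, c2) {
  ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
    ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
}

# Rasterize per-center values back to pixel resolution by nearest-center
# assignment (the semantic-segmentation surrogate).
rasterize_grid <- function(values, dim_hw, rows0, cols0) {
  ur <- sort(unique(rows0)); uc <- sort(unique(cols0))
  vm <- matrix(NA_real_, length(ur), length(uc))
  vm[cbind(match(rows0, ur), match(cols0, uc))] <- values
  ridx <- nearest_index(seq_len(dim_hw[1]) - 1L, ur)
  cidx <- nearest_index(seq_len(dim_hw[2]) - 1L, uc)
  vm[ridx, cidx, drop = FALSE]
}

nearest_index <- function(pos, centers) {
  if (length(centers) == 1L) return(rep(1L, length(pos)))
  mids <- (centers[-1L] + centers[-length(centers)]) / 2
  findInterval(pos, mids) + 1L
}
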