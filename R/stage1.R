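# Stage 1: supervised tumor segmentation at a 200 um field of view.
# Pixel-level tumor annotations (in the synthetic setting, the generator's
# ground-truth masks; in the real study, a pathologist's) train a patch
# classifier whose per-patch confidences are rasterised back to pixels by
# nearest-center assignment and thresholded into a binary tumor mask.

#' Stage-1 configuration
#'
#' @param fov_um Field of view, micrometres (200 by default).
#' @param stride_train_px Training-grid stride; default half the patch.
#' @param stride_infer_px Inference-grid stride controlling mask granularity.
#' @param threshold Tumor-call confidence threshold in `(0, 1)`.
#' @param backend Patch-learner backend (forest by default: tumor textures
#'   sit between bright background/necrosis and dark folds, which a linear
#'   boundary cannot carve out).
#' @param max_patches Cap on training patches after class balancing.
#' @return A list of settings.
#' @export
stage1_config <- function(fov_um = 200, stride_train_px = NULL,
                          stride_infer_px = 16L, threshold = 0.5,
                          backend = "forest", max_patches = 4000L) {
  stopifnot(threshold > 0, threshold < 1)
  list(fov_um = fov_um, stride_train_px = stride_train_px,
       stride_infer_px = as.integer(stride_infer_px), threshold = threshold,
       backend = backend, max_patches = as.integer(max_patches))
}

#' Train the tumor segmenter (stage 1)
#'
#' @param slides Named list of `slide_image` (>= 2, with both tumor and
#'   non-tumor content overall).
#' @param tumor_masks Named list (by slide id) of logical tumor masks or
#'   `class_mask` objects congruent with each slide.
#' @param config A [stage1_config()].
#' @param seed Integer seed (drives patch subsampling and the backend).
#' @return An object of class `tumor_segmenter` with the fitted learner and
#'   a training log.
#' @export
train_tumor_segmenter <- function(slides, tumor_masks,
                                  config = stage1_config(), seed = 1) {
  feats <- list(); labs <- list()
  for (sid in names(slides)) {
    sl <- slides[[sid]]
    m <- as_mask_matrix(tumor_masks[[sid]])
    check_congruent(m, sl$pixels[, , 1])
    patch_px <- fov_to_pixels(config$fov_um, sl$resolution_um_per_px)
    stride <- config$stride_train_px %||% max(1L, patch_px %/% 2L)
    ctr <- patch_grid_centers(dim(m), patch_px, stride)
    st <- slide_stats(sl)
    feats[[sid]] <- patch_features(st, ctr, patch_px)
    labs[[sid]] <- ifelse(m[cbind(ctr[, 1] + 1L, ctr[, 2] + 1L)],
                          "tumor", "other")
  }
  x <- do.call(rbind, feats)
  y <- unlist(labs, use.names = FALSE)
  keep <- balance_classes(y, seed, "stage1_balance")
  if (length(keep) > config$max_patches) {
    keep <- with_seed(seed, "stage1_cap",
                      sort(sample(keep, config$max_patches)))
  }
  learner <- fit_patch_learner(patch_learner(config$backend),
                               x[keep, , drop = FALSE], y[keep], seed = seed)
  structure(list(learner = learner, config = config, log = learner$log),
            class = "tumor_segmenter")
}

#' Segment tumor on a slide (stage-1 inference)
#'
#' Per-patch tumor confidences on a regular grid are rasterised to pixel
#' resolution by nearest-center assignment and thresholded. A threshold of 0
#' yields the full frame; an all-background slide yields an (almost) empty
#' mask.
#'
#' @param seg A fitted `tumor_segmenter`.
#' @param slide A `slide_image`.
#' @param threshold Optional override of the configured tumor-call threshold.
#' @return A `class_mask` of class `"tumor"` congruent with the slide.
#' @export
segment_tumor <- function(seg, slide, threshold = NULL) {
  stopifnot(inherits(seg, "tumor_segmenter"))
  thr <- threshold %||% seg$config$threshold
  conf <- tumor_confidence_raster(seg, slide)
  class_mask(slide$slide_id, "tumor", conf >= thr)
}

tumor_confidence_raster <- function(seg, slide) {
  patch_px <- fov_to_pixels(seg$config$fov_um, slide$resolution_um_per_px)
  dims <- dim(slide$pixels)[1:2]
  ctr <- patch_grid_centers(dims, patch_px, seg$config$stride_infer_px)
  st <- slide_stats(slide)
  conf <- predict_confidence(seg$learner,
                             patch_features(st, ctr, patch_px))[, "tumor"]
  rasterize_grid(conf, dims, ctr[, 1], ctr[, 2])
}

#' Intersection-over-union of two binary masks
#' @param a,b Logical matrices or `class_mask` objects of equal shape.
#' @return `|a & b| / |a | b|`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  check_congruent(a, b)
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
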