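# Stage 2: the weakly supervised core. Tumor regions found by stage 1 are
# relabeled with the *patient's* outcome group (PFI_S / PFI_L) -- a weak,
# noisy label for any individual region -- and a patch classifier at a
# 500 um field of view learns which tumor features associate with which
# group. Its per-pixel confidences inside the tumor mask are the raw
# material for the digital-biomarker filter of stage 3.

#' Stage-2 configuration
#'
#' @param fov_um Field of view, micrometres (500 by default).
#' @param stride_px Sampling-grid stride; default half the patch.
#' @param stride_infer_px Confidence-map inference stride.
#' @param backend Patch-learner backend. Linear discriminant by default:
#'   with weak labels a linear model's confidence keeps extrapolating away
#'   from the boundary, so regions that look purely like one group reach
#'   high confidence even though a fraction of their training labels is
#'   discordant.
#' @param balance Balance classes by subsampling the majority (default TRUE).
#' @return A list of settings.
#' @export
stage2_config <- function(fov_um = 500, stride_px = NULL,
                          stride_infer_px = 64L, backend = "lda",
                          balance = TRUE) {
  list(fov_um = fov_um, stride_px = stride_px,
       stride_infer_px = as.integer(stride_infer_px), backend = backend,
       balance = balance)
}

#' Build the weak training set (outcome labels on tumor patches)
#'
#' Samples patch centers on a grid inside each slide's tumor mask and labels
#' every patch with the outcome group of the slide's patient. Classes are
#' balanced by subsampling the majority class; patient and slide provenance
#' is retained per patch.
#'
#' @param slides Named list of `slide_image`.
#' @param tumor_masks Named list (by slide id) of tumor masks (stage-1
#'   output or ground truth).
#' @param outcomes Named character vector: patient id -> `"PFI_S"`/`"PFI_L"`.
#' @param config A [stage2_config()].
#' @param seed Integer seed (drives the balancing subsample).
#' @return An object of class `weak_set`: `features`, `labels` (factor),
#'   `patient_id`, `slide_id`, `centers`, `fov_um`.
#' @export
build_weak_set <- function(slides, tumor_masks, outcomes,
                           config = stage2_config(), seed = 1) {
  feats <- list(); labs <- list(); pids <- list(); sids <- list()
  ctrs <- list()
  for (sid in names(slides)) {
    sl <- slides[[sid]]
    if (!sl$patient_id %in% names(outcomes)) {
      stop("slide '", sid, "' maps to patient '", sl$patient_id,
           "' which has no outcome label")
    }
    m <- as_mask_matrix(tumor_masks[[sid]])
    check_congruent(m, sl$pixels[, , 1])
    patch_px <- fov_to_pixels(config$fov_um, sl$resolution_um_per_px)
    stride <- config$stride_px %||% max(1L, patch_px %/% 2L)
    ctr <- patch_grid_centers(dim(m), patch_px, stride)
    inside <- m[cbind(ctr[, 1] + 1L, ctr[, 2] + 1L)]
    ctr <- ctr[inside, , drop = FALSE]
    if (!nrow(ctr)) next
    st <- slide_stats(sl)
    feats[[sid]] <- patch_features(st, ctr, patch_px)
    labs[[sid]] <- rep(unname(outcomes[sl$patient_id]), nrow(ctr))
    pids[[sid]] <- rep(sl$patient_id, nrow(ctr))
    sids[[sid]] <- rep(sid, nrow(ctr))
    ctrs[[sid]] <- ctr
  }
  x <- do.call(rbind, feats)
  y <- unlist(labs, use.names = FALSE)
  pid <- unlist(pids, use.names = FALSE)
  sid <- unlist(sids, use.names = FALSE)
  ctr <- do.call(rbind, ctrs)
  if (is.null(x) || nrow(x) == 0L) {
    stop("no tumor patches available to build the weak set")
  }
  if (isTRUE(config$balance)) {
    keep <- balance_classes(y, seed, "weak_balance")
    x <- x[keep, , drop = FALSE]; y <- y[keep]; pid <- pid[keep]
    sid <- sid[keep]; ctr <- ctr[keep, , drop = FALSE]
  }
  structure(list(features = x, labels = factor(y, c("PFI_S", "PFI_L")),
                 patient_id = pid, slide_id = sid, centers = ctr,
                 fov_um = config$fov_um),
            class = "weak_set")
}

#' Train the outcome-association model (stage 2)
#'
#' @param weak_set A [build_weak_set()] result with both classes present.
#' @param config A [stage2_config()].
#' @param seed Integer seed.
#' @return An object of class `outcome_model`.
#' @export
train_outcome_model <- function(weak_set, config = stage2_config(),
                                seed = 1) {
  stopifnot(inherits(weak_set, "weak_set"))
  learner <- fit_patch_learner(patch_learner(config$backend),
                               weak_set$features, weak_set$labels,
                               seed = seed)
  structure(list(learner = learner, config = config, log = learner$log),
            class = "outcome_model")
}

#' Per-pixel outcome confidences inside the tumor mask
#'
#' Runs the stage-2 model over a dense grid, rasterises confidences by
#' nearest-center assignment and masks them to the tumor: outside the tumor
#' the map is undefined (`NA`). `conf_short + conf_long = 1` wherever
#' defined. An empty tumor mask yields a flagged, all-`NA` map.
#'
#' @param model A fitted `outcome_model`.
#' @param slide A `slide_image`.
#' @param tumor_mask Stage-1 tumor mask for the slide.
#' @return An object of class `confidence_map`: `slide_id`, matrices
#'   `conf_short` and `conf_long`, the `tumor` mask, `resolution_um_per_px`
#'   and an `empty` flag.
#' @export
infer_confidence <- function(model, slide, tumor_mask) {
  stopifnot(inherits(model, "outcome_model"))
  m <- as_mask_matrix(tumor_mask)
  check_congruent(m, slide$pixels[, , 1])
  dims <- dim(m)
  if (!any(m)) {
    na <- matrix(NA_real_, dims[1], dims[2])
    return(structure(list(slide_id = slide$slide_id, conf_short = na,
                          conf_long = na, tumor = m,
                          resolution_um_per_px = slide$resolution_um_per_px,
                          empty = TRUE),
                     class = "confidence_map"))
  }
  patch_px <- fov_to_pixels(model$config$fov_um, slide$resolution_um_per_px)
  ctr <- patch_grid_centers(dims, patch_px, model$config$stride_infer_px)
  st <- slide_stats(slide)
  conf <- predict_confidence(model$learner,
                             patch_features(st, ctr, patch_px))
  cs <- rasterize_grid(conf[, "PFI_S"], dims, ctr[, 1], ctr[, 2])
  cs[!m] <- NA_real_
  cl <- 1 - cs
  structure(list(slide_id = slide$slide_id, conf_short = cs, conf_long = cl,
                 tumor = m, resolution_um_per_px = slide$resolution_um_per_px,
                 empty = FALSE),
            class = "confidence_map")
}
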