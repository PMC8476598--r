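# Stage 3: the refined biomarker segmenter, trained on curated
# digital-biomarker annotations at a 200 um field of view, in replicate
# with identical training parameters (replicates differ only in seed).

#' Stage-3 configuration
#'
#' @param fov_um Field of view, micrometres (200 by default).
#' @param stride_px Training-grid stride; default half the patch.
#' @param backend Patch-learner backend (probability forest by default:
#'   curated annotations inherit some mislabeled pixels from the weak
#'   stage-2 masks, and forests tolerate that residual label noise well).
#' @param max_patches Cap on training patches after balancing.
#' @return A list of settings.
#' @export
stage3_config <- function(fov_um = 200, stride_px = NULL, backend = "forest",
                          max_patches = 4000L) {
  list(fov_um = fov_um, stride_px = stride_px, backend = backend,
       max_patches = as.integer(max_patches))
}

#' Train refined biomarker models (stage 3), one per seed
#'
#' Samples patches whose centers lie in the curated `dbm_short` /
#' `dbm_long` masks and fits one model per seed with identical parameters,
#' emulating replicate training runs.
#'
#' @param slides Named list of `slide_image`.
#' @param curated Named list (by slide id) of curated `dbm_masks`.
#' @param config A [stage3_config()].
#' @param seeds Integer vector; one replicate model per seed.
#' @return List of `refined_model` objects (`learner`, `replicate_id`,
#'   `seed`, `config`, `log`).
#' @export
train_refined_model <- function(slides, curated, config = stage3_config(),
                                seeds = c(1L, 2L)) {
  feats <- list(); labs <- list()
  for (sid in names(slides)) {
    sl <- slides[[sid]]
    dbm <- curated[[sid]]
    if (is.null(dbm)) next
    patch_px <- fov_to_pixels(config$fov_um, sl$resolution_um_per_px)
    stride <- config$stride_px %||% max(1L, patch_px %/% 2L)
    st <- NULL
    for (cls in c("dbm_short", "dbm_long")) {
      m <- dbm[[cls]]$mask
      if (!any(m)) next
      ctr <- patch_grid_centers(dim(m), patch_px, stride)
      inside <- m[cbind(ctr[, 1] + 1L, ctr[, 2] + 1L)]
      ctr <- ctr[inside, , drop = FALSE]
      if (!nrow(ctr)) next
      if (is.null(st)) st <- slide_stats(sl)
      key <- paste0(sid, ":", cls)
      feats[[key]] <- patch_features(st, ctr, patch_px)
      labs[[key]] <- rep(cls, nrow(ctr))
    }
  }
  x <- do.call(rbind, feats)
  y <- unlist(labs, use.names = FALSE)
  for (cls in c("dbm_short", "dbm_long")) {
    if (is.null(x) || !any(y == cls)) {
      stop("no '", cls, "' annotations anywhere in the training cohort; ",
           "cannot train the refined model")
    }
  }
  lapply(seq_along(seeds), function(k) {
    seed <- seeds[k]
    keep <- balance_classes(y, seed, "stage3_balance")
    if (length(keep) > config$max_patches) {
      keep <- with_seed(seed, "stage3_cap",
                        sort(sample(keep, config$max_patches)))
    }
    learner <- fit_patch_learner(patch_learner(config$backend),
                                 x[keep, , drop = FALSE], y[keep],
                                 seed = seed)
    structure(list(learner = learner, config = config, replicate_id = k,
                   seed = seed, log = learner$log),
              class = "refined_model")
  })
}
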