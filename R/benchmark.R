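# End-to-end orchestration: train the three stages on one cohort, score
# another, and benchmark recovery of the planted ground truth across seeds.

#' Pipeline configuration bundling all stage settings
#'
#' @param stage1,stage2,stage3,inference Per-stage configuration lists.
#' @param dbm_threshold Confidence threshold for the biomarker filter
#'   (default 0.9).
#' @param min_focus_um Minimum biomarker focus size, micrometres.
#' @param replicates Number of replicate stage-3 trainings.
#' @return A list of settings.
#' @export
pipeline_config <- function(stage1 = stage1_config(),
                            stage2 = stage2_config(),
                            stage3 = stage3_config(),
                            inference = inference_config(),
                            dbm_threshold = 0.9,
                            min_focus_um = 200,
                            replicates = 1L) {
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
       inference = inference, dbm_threshold = dbm_threshold,
       min_focus_um = min_focus_um, replicates = as.integer(replicates))
}

#' Train stages 1-3 on a cohort
#'
#' Stage 1 is trained on the cohort's tumor annotations; its *predicted*
#' tumor masks are relabeled with patient outcome for stage 2; stage 2's
#' confidence maps are filtered at `dbm_threshold` / `min_focus_um` and
#' curated against the cohort's exclusion masks (necrosis + artifact, the
#' automated stand-in for the pathologist's review); stage 3 is trained in
#' replicate on the curated annotations.
#'
#' @param cohort A `cohort` (synthetic, with ground truth).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return Object of class `dbm_pipeline`: `nn1`, `nn2`, `nn3` (list of
#'   replicates), `config`, `curated`.
#' @export
train_pipeline <- function(cohort, config = pipeline_config(), seed = 1) {
  truth_tumor <- lapply(cohort$truth, `[[`, "tumor")
  nn1 <- train_tumor_segmenter(cohort$slides, truth_tumor,
                               config = config$stage1, seed = seed)
  pred_tumor <- lapply(cohort$slides, function(sl) segment_tumor(nn1, sl))
  outcomes <- cohort_outcomes(cohort)
  weak <- build_weak_set(cohort$slides, pred_tumor, outcomes,
                         config = config$stage2, seed = seed)
  nn2 <- train_outcome_model(weak, config = config$stage2, seed = seed)
  curated <- lapply(names(cohort$slides), function(sid) {
    cm <- infer_confidence(nn2, cohort$slides[[sid]], pred_tumor[[sid]])
    dbm <- filter_high_confidence(cm, threshold = config$dbm_threshold,
                                  min_focus_um = config$min_focus_um)
    tr <- cohort$truth[[sid]]
    curate_annotations(dbm, list(tr$necrosis, tr$artifact))
  })
  names(curated) <- names(cohort$slides)
  seeds <- derive_seed(seed, "stage3") + seq_len(config$replicates) - 1L
  nn3 <- train_refined_model(cohort$slides, curated,
                             config = config$stage3, seeds = seeds)
  structure(list(nn1 = nn1, nn2 = nn2, nn3 = nn3, config = config,
                 curated = curated),
            class = "dbm_pipeline")
}

#' Patient-level outcome lookup from cohort metadata
#' @param cohort A `cohort`.
#' @return Named character vector, patient id -> group.
#' @export
cohort_outcomes <- function(cohort) {
  md <- unique(cohort$metadata[, c("patient_id", "group")])
  stats::setNames(md$group, md$patient_id)
}

#' Score every slide of a cohort with a trained pipeline
#'
#' @param pipeline A `dbm_pipeline`.
#' @param cohort A `cohort`.
#' @param replicate Which stage-3 replicate to use (default 1).
#' @param return_masks Also collect per-slide predicted masks.
#' @return Data frame of slide scores (plus `outcome`); with masks, a list
#'   `scores` + `masks`.
#' @export
score_cohort <- function(pipeline, cohort, replicate = 1L,
                         return_masks = FALSE) {
  nn3 <- pipeline$nn3[[replicate]]
  outcomes <- cohort_outcomes(cohort)
  res <- lapply(names(cohort$slides), function(sid) {
    run_inference(pipeline$nn1, nn3, cohort$slides[[sid]],
                  config = pipeline$config$inference,
                  return_masks = return_masks)
  })
  scores <- do.call(rbind, lapply(res, function(r) {
    if (return_masks) r$score else r
  }))
  scores$outcome <- unname(outcomes[
    cohort$metadata$patient_id[match(scores$slide_id,
                                     cohort$metadata$slide_id)]])
  if (return_masks) {
    masks <- lapply(res, `[[`, "masks")
    names(masks) <- scores$slide_id
    list(scores = scores, masks = masks)
  } else {
    scores
  }
}

#' End-to-end synthetic benchmark
#'
#' For each seed: generates a training and a held-out test cohort, trains
#' the full pipeline on the training cohort, selects the rank-order ratio
#' cutoff by best fit on the *training* slide scores (the same post-hoc
#' selection the workflow prescribes, kept patient-disjoint from the test
#' set), scores the test cohort, and reports held-out slide accuracy plus
#' recovery of the planted ground truth (tumor-mask IoU and short-biomarker
#' IoU against the planted short_like texture inside tumor).
#'
#' @param train_spec,test_spec `cohort_spec`s for the training and held-out
#'   cohorts.
#' @param config A [pipeline_config()].
#' @param n_seeds Number of independent repetitions.
#' @param base_seed Base seed; repetition k uses `base_seed + k - 1`.
#' @return Data frame, one row per seed: `seed`, `cutoff`, `accuracy_pct`,
#'   `tumor_iou`, `dbm_short_iou`, with a `summary` attribute (mean, sd).
#' @export
end_to_end_benchmark <- function(train_spec, test_spec,
                                 config = pipeline_config(),
                                 n_seeds = 5, base_seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    seed <- base_seed + k - 1
    train_co <- generate_cohort(train_spec, derive_seed(seed, "bench_train"))
    test_co <- generate_cohort(test_spec, derive_seed(seed, "bench_test"))
    pipe <- tryCatch(
      train_pipeline(train_co, config = config, seed = seed),
      error = function(e) {
        if (!grepl("annotations anywhere in the training cohort",
                   conditionMessage(e))) stop(e)
        NULL  # no biomarker class survived filtering: pipeline abstains
      }
    )
    if (is.null(pipe)) {
      outcomes <- cohort_outcomes(test_co)
      md <- test_co$metadata
      pred <- stats::setNames(
        with_seed(seed, "abstain_chance",
                  sample(c("PFI_S", "PFI_L"), nrow(md), replace = TRUE)),
        md$slide_id)
      metrics <- evaluate_predictions(
        pred, stats::setNames(unname(outcomes[md$patient_id]), md$slide_id))
      return(data.frame(seed = seed, cutoff = NA_real_,
                        accuracy_pct = metrics$accuracy,
                        tumor_iou = NA_real_, dbm_short_iou = NA_real_))
    }
    train_scores <- score_cohort(pipe, train_co)
    ok_train <- !train_scores$flagged & !is.na(train_scores$ratio)
    cutoff <- if (any(ok_train)) {
      ts <- train_scores[ok_train, ]
      best_fit_cutoff(ts, stats::setNames(ts$outcome, ts$slide_id))
    } else 30
    sc <- score_cohort(pipe, test_co, return_masks = TRUE)
    # slides with no biomarker evidence (flagged / undefined ratio) carry no
    # signal; score them at chance (seeded coin flip) so the negative
    # control is well defined
    defined <- !sc$scores$flagged & !is.na(sc$scores$ratio)
    pred <- stats::setNames(rep(NA_character_, nrow(sc$scores)),
                            sc$scores$slide_id)
    if (any(defined)) {
      cls <- classify_slides(sc$scores[defined, ], cutoff = cutoff)
      pred[cls$slide_id] <- cls$prediction
    }
    if (any(!defined)) {
      pred[sc$scores$slide_id[!defined]] <- with_seed(
        seed, "abstain_chance",
        sample(c("PFI_S", "PFI_L"), sum(!defined), replace = TRUE))
    }
    metrics <- evaluate_predictions(
      pred, stats::setNames(sc$scores$outcome, sc$scores$slide_id))
    # micro-averaged (pixel-pooled) IoU over the held-out cohort
    acc <- c(tum_i = 0, tum_u = 0, dbm_i = 0, dbm_u = 0)
    for (sid in names(sc$masks)) {
      tr <- test_co$truth[[sid]]
      pm <- sc$masks[[sid]]
      truth_s <- tr$short_like & tr$tumor
      acc <- acc + c(sum(pm$tumor & tr$tumor), sum(pm$tumor | tr$tumor),
                     sum(pm$dbm_short & truth_s),
                     sum(pm$dbm_short | truth_s))
    }
    data.frame(seed = seed, cutoff = cutoff,
               accuracy_pct = metrics$accuracy,
               tumor_iou = acc[["tum_i"]] / acc[["tum_u"]],
               dbm_short_iou = acc[["dbm_i"]] / acc[["dbm_u"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("accuracy_pct", "tumor_iou", "dbm_short_iou"),
    mean = c(mean(out$accuracy_pct), mean(out$tumor_iou),
             mean(out$dbm_short_iou)),
    sd = c(stats::sd(out$accuracy_pct), stats::sd(out$tumor_iou),
           stats::sd(out$dbm_short_iou))
  )
  out
}

#' Default desk-scale benchmark cohort specifications
#'
#' The training cohort keeps the study's structure at reduced size (16
#' patients, 2-3 slides each); the held-out cohort mirrors the 22-slide
#' validation set (22 patients, one slide each, 11 per group).
#'
#' @param mixture_bias,texture_contrast Passed through to [cohort_spec()].
#' @return List with `train` and `test` `cohort_spec`s.
#' @export
benchmark_specs <- function(mixture_bias = 0.6, texture_contrast = 1.0) {
  list(
    train = cohort_spec(n_short_patients = 8, n_long_patients = 8,
                        slides_per_patient = c(2, 3),
                        mixture_bias = mixture_bias,
                        texture_contrast = texture_contrast),
    test = cohort_spec(n_short_patients = 11, n_long_patients = 11,
                       slides_per_patient = c(1, 1),
                       mixture_bias = mixture_bias,
                       texture_contrast = texture_contrast)
  )
}
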