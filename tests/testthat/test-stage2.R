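# Weakly supervised outcome learning: weak-set construction, confidence
# maps, and patch-level behaviour under signal and under the null.

pure_texture_features <- function(name, n, fov_px, seed) {
  wsidbm:::with_seed(seed, paste0("pure_", name), {
    do.call(rbind, lapply(seq_len(n), function(i) {
      sl <- slide_image("p", "p", render_textures(fov_px, fov_px, name), 2.0)
      patch_features(slide_stats(sl),
                     cbind(fov_px %/% 2L, fov_px %/% 2L), fov_px)
    }))
  })
}

test_that("weak sets balance classes and stay inside the tumor mask", {
  co <- mini_cohort()
  truth <- lapply(co$truth, `[[`, "tumor")
  outcomes <- cohort_outcomes(co)
  ws <- build_weak_set(co$slides, truth, outcomes,
                       config = stage2_config(stride_px = 32L), seed = 1)
  counts <- table(ws$labels)
  expect_identical(unname(counts[["PFI_S"]]), unname(counts[["PFI_L"]]))
  for (i in seq_len(nrow(ws$centers))) {
    m <- truth[[ws$slide_id[i]]]
    expect_true(m[ws$centers[i, 1] + 1L, ws$centers[i, 2] + 1L])
  }
  # labels are constant within a patient
  expect_true(all(tapply(as.character(ws$labels), ws$patient_id,
                         function(x) length(unique(x))) == 1))
})

test_that("unbalanced weak-set size equals brute-force center enumeration", {
  co <- mini_cohort()
  truth <- lapply(co$truth, `[[`, "tumor")
  cfg <- stage2_config(stride_px = 48L, balance = FALSE)
  ws <- build_weak_set(co$slides, truth, cohort_outcomes(co),
                      config = cfg, seed = 1)
  expected <- 0L
  for (sid in names(co$slides)) {
    m <- truth[[sid]]
    p2 <- 125L  # 500 um at 2 um/px -> 250 px patch
    for (r in seq(p2, nrow(m) - 1L, by = 48L)) {
      for (c in seq(p2, ncol(m) - 1L, by = 48L)) {
        if (m[r + 1L, c + 1L]) expected <- expected + 1L
      }
    }
  }
  expect_identical(nrow(ws$features), expected)
})

test_that("a slide without a patient outcome label is an error", {
  co <- mini_cohort()
  truth <- lapply(co$truth, `[[`, "tumor")
  outcomes <- cohort_outcomes(co)
  outcomes <- outcomes[-1]
  expect_error(build_weak_set(co$slides, truth, outcomes, seed = 1),
               "no outcome label")
})

test_that("the outcome model separates pure planted textures under signal", {
  co <- generate_cohort(cohort_spec(n_short_patients = 5,
                                    n_long_patients = 5,
                                    slides_per_patient = c(2, 2),
                                    slide_size_px = c(320, 320)),
                        seed = 19)
  truth <- lapply(co$truth, `[[`, "tumor")
  ws <- build_weak_set(co$slides, truth, cohort_outcomes(co),
                       config = stage2_config(stride_px = 64L), seed = 2)
  mod <- train_outcome_model(ws, seed = 2)
  fov_px <- 250L
  xs <- pure_texture_features("short_like", 40, fov_px, 21)
  xl <- pure_texture_features("long_like", 40, fov_px, 22)
  conf <- predict_confidence(mod$learner, rbind(xs, xl))
  pred <- colnames(conf)[max.col(conf, ties.method = "first")]
  truth <- rep(c("PFI_S", "PFI_L"), each = 40)
  expect_gte(mean(pred == truth), 0.75)
})

test_that("with no mixture bias, patch accuracy stays at chance", {
  accs <- vapply(1:30, function(rep) {
    spec <- cohort_spec(n_short_patients = 2, n_long_patients = 2,
                        slides_per_patient = c(1, 1),
                        slide_size_px = c(192, 192), mixture_bias = 0)
    co <- generate_cohort(spec, seed = 100 + rep)
    truth <- lapply(co$truth, `[[`, "tumor")
    ws <- build_weak_set(co$slides, truth, cohort_outcomes(co),
                         config = stage2_config(fov_um = 200,
                                                stride_px = 24L),
                         seed = rep)
    mod <- train_outcome_model(ws, config = stage2_config(fov_um = 200),
                               seed = rep)
    fov_px <- 100L
    xs <- pure_texture_features("short_like", 10, fov_px, 400 + rep)
    xl <- pure_texture_features("long_like", 10, fov_px, 500 + rep)
    conf <- predict_confidence(mod$learner, rbind(xs, xl))
    pred <- colnames(conf)[max.col(conf, ties.method = "first")]
    mean(pred == rep(c("PFI_S", "PFI_L"), each = 10))
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 1e-8)
})

test_that("confidence maps are normalized, tumor-bounded and reproducible", {
  pipe <- mini_pipeline()
  co <- mini_cohort()
  sid <- names(co$slides)[3]
  tum <- segment_tumor(pipe$nn1, co$slides[[sid]])
  cm <- infer_confidence(pipe$nn2, co$slides[[sid]], tum)
  inside <- tum$mask
  expect_true(all(abs(cm$conf_short[inside] + cm$conf_long[inside] - 1)
                  < 1e-6))
  expect_true(all(is.na(cm$conf_short[!inside])))
  expect_false(cm$empty)
  cm2 <- infer_confidence(pipe$nn2, co$slides[[sid]], tum)
  expect_identical(cm$conf_short, cm2$conf_short)
})

test_that("an empty tumor mask yields a flagged, all-NA confidence map", {
  pipe <- mini_pipeline()
  co <- mini_cohort()
  sl <- co$slides[[1]]
  empty <- matrix(FALSE, dim(sl$pixels)[1], dim(sl$pixels)[2])
  cm <- infer_confidence(pipe$nn2, sl, empty)
  expect_true(cm$empty)
  expect_true(all(is.na(cm$conf_short)))
})

test_that("a slide of pure short texture leans short in confidence", {
  pipe <- mini_pipeline()
  px <- wsidbm:::with_seed(77, "pure_slide",
                           render_textures(320, 320, "short_like"))
  sl <- slide_image("PURE-s01", "PURE", px, 2.0)
  full <- matrix(TRUE, 320, 320)
  cm <- infer_confidence(pipe$nn2, sl, full)
  expect_gt(mean(cm$conf_short), mean(cm$conf_long))
})
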