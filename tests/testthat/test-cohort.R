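small_spec <- function(...) {
  cohort_spec(slide_size_px = c(96, 96), ...)
}

test_that("cohort generation is a pure function of (spec, seed)", {
  spec <- small_spec(n_short_patients = 2, n_long_patients = 2,
                     slides_per_patient = c(1, 3))
  a <- generate_cohort(spec, seed = 4)
  b <- generate_cohort(spec, seed = 4)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 5)
  expect_false(identical(a$slides, c$slides))
})

test_that("the default cohort shape mirrors the study structure", {
  # 17 + 13 patients, 2-13 slides per patient
  co <- generate_cohort(small_spec(), seed = 1)
  md <- co$metadata
  pats <- unique(md[, c("patient_id", "group")])
  expect_identical(nrow(pats), 30L)
  expect_identical(sum(pats$group == "PFI_S"), 17L)
  expect_identical(sum(pats$group == "PFI_L"), 13L)
  expect_gte(nrow(md), 60L)
  expect_lte(nrow(md), 390L)
  per_pat <- table(md$patient_id)
  expect_true(all(per_pat >= 2 & per_pat <= 13))
  # PFI metadata respects the group definitions
  expect_true(all(md$pfi_months[md$group == "PFI_S"] <= 6))
  expect_true(all(md$pfi_months[md$group == "PFI_L"] >= 18))
})

test_that("ground-truth masks partition every slide", {
  co <- generate_cohort(small_spec(n_short_patients = 2, n_long_patients = 2,
                                   slides_per_patient = c(2, 2)), seed = 3)
  for (tr in co$truth) {
    expect_true(all(tr$tumor + tr$necrosis + tr$artifact + tr$background == 1))
    expect_identical(tr$short_like | tr$long_like | tr$neutral, tr$tumor)
    expect_false(any(tr$short_like & tr$long_like))
    expect_gt(sum(tr$tumor), 0)
  }
})

test_that("mixture bias shifts planted texture fractions between groups", {
  # recomputed from the emitted ground-truth masks at the default bias 0.6
  co <- generate_cohort(small_spec(slides_per_patient = c(2, 2)), seed = 8)
  frac <- vapply(co$truth, function(tr) sum(tr$short_like) / sum(tr$tumor),
                 numeric(1))
  grp <- co$metadata$group[match(names(frac), co$metadata$slide_id)]
  gap <- mean(frac[grp == "PFI_S"]) - mean(frac[grp == "PFI_L"])
  expect_gte(gap, 0.4)
})

test_that("outcome textures are linearly separable at full contrast", {
  # train/test split oracle on 100-px patch features
  render_batch <- function(name, n, seed) {
    wsidbm:::with_seed(seed, name, {
      lapply(seq_len(n), function(i) {
        sl <- slide_image("t", "t", render_textures(100, 100, name), 2.0)
        patch_features(slide_stats(sl), cbind(50L, 50L), 100L)
      })
    })
  }
  n <- 250
  xs <- do.call(rbind, render_batch("short_like", n, 31))
  xl <- do.call(rbind, render_batch("long_like", n, 32))
  x <- rbind(xs, xl)
  y <- factor(rep(c("s", "l"), each = n))
  idx_train <- c(1:150, n + (1:150))
  fit <- MASS::lda(x[idx_train, ], grouping = y[idx_train])
  pred <- predict(fit, x[-idx_train, ])$class
  expect_gte(mean(pred == y[-idx_train]), 0.95)
})

test_that("at contrast zero the outcome textures share one distribution", {
  a <- wsidbm:::with_seed(1, "tex", render_textures(64, 64, "short_like",
                                                    contrast = 0))
  b <- wsidbm:::with_seed(1, "tex", render_textures(64, 64, "long_like",
                                                    contrast = 0))
  expect_identical(a, b)
})

test_that("necrosis is brighter than every tumor texture by the margin", {
  lum <- function(name) mean(wsidbm:::texture_params(name, 1, 0.15)$mean)
  tumor_lums <- vapply(c("neutral", "short_like", "long_like"), lum,
                       numeric(1))
  expect_equal(lum("necrosis") - max(tumor_lums), 0.15, tolerance = 1e-9)
})

test_that("artifact rates of zero and one behave as configured", {
  none <- small_spec(n_short_patients = 2, n_long_patients = 2,
                     slides_per_patient = c(2, 2),
                     artifact_rates = list(necrosis = 0, whitespace = 0,
                                           blur = 0, fold = 0))
  co <- generate_cohort(none, seed = 2)
  for (tr in co$truth) {
    expect_identical(sum(tr$necrosis) + sum(tr$artifact), 0L)
  }
  folds <- small_spec(n_short_patients = 2, n_long_patients = 2,
                      slides_per_patient = c(2, 2),
                      artifact_rates = list(necrosis = 0, whitespace = 0,
                                            blur = 0, fold = 1))
  co <- generate_cohort(folds, seed = 2)
  for (tr in co$truth) expect_gt(sum(tr$artifact), 0)
})

test_that("long-run artifact area matches its configured expectation", {
  spec <- small_spec(n_short_patients = 25, n_long_patients = 25,
                     slides_per_patient = c(1, 1))
  co <- generate_cohort(spec, seed = 6)
  nec <- vapply(co$truth, function(tr) mean(tr$necrosis), numeric(1))
  expected <- wsidbm:::artifact_expected_fractions(spec)
  se <- sd(nec) / sqrt(length(nec))
  expect_lt(abs(mean(nec) - expected$necrosis), 3 * se)
})

test_that("degenerate cohort specifications are rejected", {
  expect_error(cohort_spec(n_short_patients = 0), "degenerate")
  expect_error(cohort_spec(artifact_rates = list(necrosis = 1.5,
                                                 whitespace = 0, blur = 0,
                                                 fold = 0)),
               "rates")
  expect_error(render_textures(10, 10, "nonexistent"), "unknown texture")
})
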