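# Ratio arithmetic, the cutoff rule, and combined-pipeline slide scoring.

test_that("ratios reproduce printed validation-table cells", {
  # slide T13, replicate 1: short 4.2%, long 9.4%
  r1 <- compute_ratio(4.2, 9.4)
  expect_equal(r1, 4.2 / 9.4, tolerance = 1e-12)
  expect_identical(display_ratio(r1), "0.4")
  # slide T03, replicate 2: short 66.5%, long 2.2%
  r2 <- compute_ratio(66.5, 2.2)
  expect_equal(r2, 66.5 / 2.2, tolerance = 1e-12)
  expect_identical(display_ratio(r2), "30.2")
})

test_that("ratio arithmetic: symmetry, epsilon floor, undefined case", {
  for (x in c(0.3, 1, 57.5)) expect_equal(compute_ratio(x, x), 1)
  # displayed-zero long percentage still yields a finite ratio
  expect_equal(compute_ratio(56.6, 0), 56.6 / 0.005)
  expect_warning(r <- compute_ratio(0, 0), "undefined ratio")
  expect_true(is.na(r))
})

test_that("the cutoff rule is >= 30 with deterministic ranking", {
  sc <- data.frame(slide_id = c("A", "B", "C", "D"),
                   ratio = c(30.2, 25.7, 30.0, 0.4))
  out <- classify_slides(sc, cutoff = 30)
  expect_identical(out$slide_id, c("D", "B", "C", "A"))  # ascending ratio
  pred <- setNames(out$prediction, out$slide_id)
  expect_identical(unname(pred["A"]), "PFI_S")  # 30.2 -> short
  expect_identical(unname(pred["B"]), "PFI_L")  # 25.7 -> long
  expect_identical(unname(pred["C"]), "PFI_S")  # boundary 30.0 -> short
  # permuting input rows permutes output identically
  out2 <- classify_slides(sc[c(3, 1, 4, 2), ], cutoff = 30)
  expect_identical(out2$prediction, out$prediction)
  expect_error(classify_slides(data.frame(slide_id = "A", ratio = NA_real_)),
               "undefined ratio")
})

test_that("increasing short area can only move a slide toward PFI_S", {
  set.seed(3)
  for (i in 1:25) {
    long <- runif(1, 0, 30); short <- runif(1, 0, 80)
    r_lo <- compute_ratio(short, long)
    r_hi <- compute_ratio(short + runif(1, 0, 20), long)
    expect_gte(r_hi, r_lo)
    p <- function(r) ifelse(r >= 30, "PFI_S", "PFI_L")
    expect_false(p(r_lo) == "PFI_S" && p(r_hi) == "PFI_L")
  }
})

test_that("slide scores conserve area and respect the tumor gate", {
  pipe <- mini_pipeline()
  co <- mini_cohort()
  for (sid in names(co$slides)[c(1, 4, 9)]) {
    res <- run_inference(pipe$nn1, pipe$nn3[[1]], co$slides[[sid]],
                         config = pipe$config$inference,
                         return_masks = TRUE)
    s <- res$score
    expect_equal(s$short_dbm_pct + s$long_dbm_pct + s$unclassified_pct, 100,
                 tolerance = 1e-6)
    expect_true(all(!res$masks$dbm_short | res$masks$tumor))
    expect_true(all(!res$masks$dbm_long | res$masks$tumor))
    expect_false(any(res$masks$dbm_short & res$masks$dbm_long))
    expect_false(s$flagged)
  }
})

test_that("a tumor-free slide is flagged with a warning, not scored", {
  pipe <- mini_pipeline()
  expect_warning(
    s <- run_inference(pipe$nn1, pipe$nn3[[1]], background_slide(),
                       config = pipe$config$inference),
    "empty tumor mask")
  expect_true(s$flagged)
  expect_true(is.na(s$ratio))
})

test_that("a pure short-texture tumor scores short-dominant", {
  pipe <- mini_pipeline()
  px <- wsidbm:::with_seed(42, "pure_short_slide",
                           render_textures(320, 320, "short_like"))
  sl <- slide_image("PURE-s02", "PURE", px, 2.0)
  s <- run_inference(pipe$nn1, pipe$nn3[[1]], sl,
                     config = pipe$config$inference)
  expect_false(s$flagged)
  expect_gt(s$short_dbm_pct, s$long_dbm_pct)
})

test_that("the cutoff sweep reports but does not modify classifications", {
  sc <- data.frame(slide_id = sprintf("S%02d", 1:6),
                   ratio = c(0.5, 2, 8, 40, 90, 300))
  out <- setNames(c("PFI_L", "PFI_L", "PFI_L", "PFI_S", "PFI_S", "PFI_S"),
                  sc$slide_id)
  sw <- cutoff_sweep(sc, out)
  expect_true(any(sw$accuracy == 100))
  best <- wsidbm:::best_fit_cutoff(sc, out)
  expect_gt(best, 8); expect_lte(best, 40)
})
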