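# Connected components, the minimum-focus filter, and curation.

fake_conf_map <- function(conf_short, tumor = NULL, res = 2.0) {
  if (is.null(tumor)) tumor <- !is.na(conf_short)
  cs <- conf_short
  cs[!tumor] <- NA_real_
  structure(list(slide_id = "F01-s01", conf_short = cs, conf_long = 1 - cs,
                 tumor = tumor, resolution_um_per_px = res, empty = FALSE),
            class = "confidence_map")
}

test_that("component labeling agrees with brute-force flood fill", {
  set.seed(1234)
  for (trial in 1:200) {
    h <- sample(5:64, 1); w <- sample(5:64, 1)
    m <- matrix(runif(h * w) < runif(1, 0.2, 0.8), h, w)
    for (conn in c(8, 4)) {
      expect_identical(canonical_labels(label_components(m, conn)),
                       canonical_labels(flood_fill_label(m, conn)))
    }
  }
})

test_that("the minimum-focus rule keeps only sufficiently large foci", {
  # discs of equivalent diameter ~148 um and ~252 um at 2 um/px
  m <- matrix(FALSE, 200, 320)
  m[centered_disc(200, 320, 37, cy = 100, cx = 70)] <- TRUE
  m[centered_disc(200, 320, 63, cy = 100, cx = 230)] <- TRUE
  small_px <- sum(centered_disc(200, 320, 37, cy = 100, cx = 70))
  expect_lt(equivalent_diameter_um(small_px, 2), 200)
  out <- filter_min_focus(m, min_focus_um = 200, resolution_um_per_px = 2)
  # only the large disc survives
  expect_identical(out, m & (col(m) > 150))
})

test_that("high-confidence filtering thresholds, sizes and records provenance", {
  set.seed(5)
  conf <- matrix(runif(120 * 120, 0.55, 0.999), 120, 120)
  cm <- fake_conf_map(conf)
  # all confidences < 1: threshold 1 empties both classes
  top <- filter_high_confidence(cm, threshold = 1, min_focus_um = 10)
  expect_identical(sum(top$dbm_short$mask) + sum(top$dbm_long$mask), 0L)

  # monotonicity in the threshold
  lo <- filter_high_confidence(cm, threshold = 0.8, min_focus_um = 20)
  hi <- filter_high_confidence(cm, threshold = 0.9, min_focus_um = 20)
  expect_true(all(!hi$dbm_short$mask | lo$dbm_short$mask))
  expect_lte(sum(hi$dbm_short$mask), sum(lo$dbm_short$mask))

  # disjoint classes, tumor containment, provenance
  expect_false(any(lo$dbm_short$mask & lo$dbm_long$mask))
  expect_true(all(!lo$dbm_short$mask | cm$tumor))
  expect_identical(lo$provenance$threshold, 0.8)
  expect_error(filter_high_confidence(cm, threshold = 0.4), "threshold")
})

test_that("the confidence filter is idempotent", {
  set.seed(6)
  conf <- matrix(runif(150 * 150), 150, 150)
  first <- filter_high_confidence(fake_conf_map(conf), threshold = 0.7,
                                  min_focus_um = 100)
  # feed the filtered mask back in as a saturated confidence map
  conf2 <- matrix(0, 150, 150)
  conf2[first$dbm_short$mask] <- 1
  second <- filter_high_confidence(fake_conf_map(conf2), threshold = 0.7,
                                   min_focus_um = 100)
  expect_identical(second$dbm_short$mask, first$dbm_short$mask)
})

test_that("biomarker overlays are exported with provenance for review", {
  set.seed(31)
  px <- array(runif(40 * 40 * 3), dim = c(40, 40, 3))
  sl <- slide_image("V01-s01", "V01", px, 2.0)
  conf <- matrix(0, 40, 40); conf[5:20, 5:20] <- 0.95
  dbm <- filter_high_confidence(fake_conf_map(conf), threshold = 0.9,
                                min_focus_um = 10)
  path <- file.path(withr::local_tempdir(), "overlay.png")
  write_dbm_overlay(sl, dbm, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(wsidbm:::sidecar_path(path),
                              simplifyVector = TRUE)
  expect_identical(meta$slide_id, "V01-s01")
  expect_equal(meta$threshold, 0.9)
  # tinted region is redder than the original
  out <- png::readPNG(path)
  expect_gt(mean(out[5:20, 5:20, 1]) - mean(px[5:20, 5:20, 1]), 0.05)
})

test_that("curation subtracts exclusions and re-applies the focus filter", {
  conf <- matrix(0, 200, 320)
  disc <- centered_disc(200, 320, 80)       # one ~320 um focus
  conf[disc] <- 0.95
  dbm <- filter_high_confidence(fake_conf_map(conf), threshold = 0.9,
                                min_focus_um = 200)
  expect_identical(dbm$dbm_short$mask, disc)

  # empty exclusions: unchanged
  none <- curate_annotations(dbm, list(matrix(FALSE, 200, 320)))
  expect_identical(none$dbm_short$mask, disc)

  # a focus wholly inside necrosis disappears
  gone <- curate_annotations(dbm, list(disc))
  expect_identical(sum(gone$dbm_short$mask), 0L)

  # an artifact band splitting the focus leaves fragments that must
  # individually pass the 200 um rule: here the left piece does, the right
  # cap does not
  band <- matrix(FALSE, 200, 320)
  band[, 166:185] <- TRUE                   # off-center split
  split <- curate_annotations(dbm, list(band))
  left <- disc & col(disc) < 166
  right <- disc & col(disc) > 185
  expect_lt(equivalent_diameter_um(sum(right), 2), 200)
  expect_gte(equivalent_diameter_um(sum(left), 2), 200)
  expect_identical(split$dbm_short$mask, left)
})
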