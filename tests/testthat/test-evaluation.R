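# Validation-table fixture invariants, diagnostic metrics, and replicate
# concordance.

test_that("the bundled fixture satisfies its structural invariants", {
  tab <- load_table3()
  expect_identical(nrow(tab), 44L)
  for (rep in 1:2) {
    sub <- tab[tab$replicate == rep, ]
    expect_identical(nrow(sub), 22L)
    expect_identical(length(unique(sub$slide_id)), 22L)
    # printed in ascending ratio order
    expect_true(all(diff(sub$ratio[order(sub$printed_row)]) >= 0))
  }
  # outcome is a slide property, identical across replicates
  by_slide <- tapply(tab$outcome, tab$slide_id,
                     function(x) length(unique(x)))
  expect_true(all(by_slide == 1))
  # 11 short and 11 long outcome slides
  r2 <- tab[tab$replicate == 2, ]
  expect_identical(sum(r2$outcome == "Short"), 11L)
  expect_identical(sum(r2$outcome == "Long"), 11L)
})

test_that("half-up rounding matches the published whole-percent figures", {
  expect_identical(round_half_up(c(72.7, 90.9, 88.9, 81.8)),
                   c(73, 91, 89, 82))
  expect_identical(round_half_up(62.5), 63)  # half goes up, not to even
})

test_that("replicate-2 confusion matrix and metrics match the published report", {
  ev <- evaluate_table3(replicate = 2, cutoff = 30)
  m <- ev$metrics
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(8L, 3L, 10L, 1L))
  expect_identical(round_half_up(m$sensitivity), 73)
  expect_identical(round_half_up(m$specificity), 91)
  expect_identical(round_half_up(m$ppv), 89)
  expect_identical(round_half_up(m$accuracy), 82)
  expect_identical(m$n_correct, 18L)
})

test_that("degenerate prediction vectors give the expected extremes", {
  tab <- load_table3()
  r2 <- tab[tab$replicate == 2, ]
  truth <- setNames(r2$outcome, r2$slide_id)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  all_long <- evaluate_predictions(
    setNames(rep("Long", 22), r2$slide_id), truth)
  expect_equal(all_long$sensitivity, 0)
  expect_equal(all_long$specificity, 100)
})

test_that("mismatched slide sets are an error listing the difference", {
  pred <- c(A = "PFI_S", B = "PFI_L")
  out <- c(B = "PFI_L", C = "PFI_S")
  expect_error(evaluate_predictions(pred, out), "A")
  expect_error(evaluate_predictions(pred, out), "C")
})

test_that("metrics equal a brute-force confusion recount on random vectors", {
  set.seed(77)
  for (trial in 1:1000) {
    n <- sample(4:40, 1)
    ids <- sprintf("S%03d", seq_len(n))
    pred <- setNames(sample(c("PFI_S", "PFI_L"), n, TRUE), ids)
    truth <- setNames(sample(c("PFI_S", "PFI_L"), n, TRUE), ids)
    m <- evaluate_predictions(pred, truth)
    ref <- naive_confusion(pred[ids], truth[ids])
    expect_identical(c(m$tp, m$fp, m$tn, m$fn), unname(ref))
    expect_equal(m$accuracy, 100 * (ref["tp"] + ref["tn"]) / n,
                 ignore_attr = TRUE)
    if (ref["tp"] + ref["fn"] > 0) {
      expect_equal(m$sensitivity,
                   100 * ref["tp"] / (ref["tp"] + ref["fn"]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("replicate concordance reports the misclassified-subset relation", {
  tab <- load_table3()
  preds <- lapply(1:2, function(rep) {
    sub <- classify_slides(tab[tab$replicate == rep, ], cutoff = 30)
    setNames(sub$prediction, sub$slide_id)
  })
  r2 <- tab[tab$replicate == 2, ]
  truth <- setNames(as_pfi_group(r2$outcome), r2$slide_id)
  rc <- replicate_concordance(preds[[1]], preds[[2]], truth)
  expect_true(rc$rep2_subset_of_rep1)
  expect_identical(rc$misclassified_rep2, sort(c("T02", "T07", "T08", "T22")))
  expect_identical(rc$misclassified_rep1,
                   sort(c("T02", "T07", "T08", "T19", "T21", "T22")))

  # identical predictions: full agreement, subset trivially true
  rc_same <- replicate_concordance(preds[[2]], preds[[2]], truth)
  expect_equal(rc_same$agreement_pct, 100)
  expect_true(rc_same$rep2_subset_of_rep1)

  # constructed disjoint misclassification sets: subset relation is false
  ids <- c("A", "B", "C", "D")
  truth2 <- setNames(c("PFI_S", "PFI_S", "PFI_L", "PFI_L"), ids)
  p1 <- setNames(c("PFI_L", "PFI_S", "PFI_L", "PFI_L"), ids)  # misses A
  p2 <- setNames(c("PFI_S", "PFI_S", "PFI_S", "PFI_L"), ids)  # misses C
  expect_false(replicate_concordance(p1, p2, truth2)$rep2_subset_of_rep1)
})
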