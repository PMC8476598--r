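# Evaluation surface: the bundled validation-set fixture, diagnostic-test
# metrics with PFI_S as the positive class, replicate concordance, and the
# end-to-end synthetic benchmark.

#' Load the bundled validation-set fixture
#'
#' 44 rows (22 test slides x 2 replicate trainings of the refined model):
#' per slide, the long- and short-biomarker area percentages (of tumor
#' area), the printed short/long ratio, the actual outcome group and the
#' published model prediction. `long_truncated` marks long percentages that
#' display as 0.0 without being true zeros; the printed ratio column was
#' computed from unrounded values and is the evaluation surface.
#'
#' @return Data frame with columns `replicate`, `printed_row`, `slide_id`,
#'   `long_dbm_pct`, `short_dbm_pct`, `ratio`, `outcome`, `prediction`,
#'   `long_truncated`.
#' @export
load_table3 <- function() {
  path <- system.file("extdata", "table3_fixture.csv", package = "wsidbm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$long_truncated <- as.logical(df$long_truncated)
  df
}

#' Map Short/Long labels to PFI groups (and back)
#' @param x Character vector of `"Short"`/`"Long"` or `"PFI_S"`/`"PFI_L"`.
#' @return Character vector in `"PFI_S"`/`"PFI_L"` form.
#' @export
as_pfi_group <- function(x) {
  out <- ifelse(x %in% c("Short", "PFI_S"), "PFI_S",
                ifelse(x %in% c("Long", "PFI_L"), "PFI_L", NA_character_))
  if (any(is.na(out) & !is.na(x))) {
    stop("unknown outcome label(s): ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  }
  out
}

#' Round half away from zero
#'
#' Whole-percent rounding used for comparison with published figures
#' (72.7 -> 73, 90.9 -> 91, 88.9 -> 89, 81.8 -> 82).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Confusion-matrix metrics for slide classification
#'
#' Positive class is PFI_S throughout. Metrics are kept at full precision;
#' rounding to whole percent happens only at print time.
#'
#' @param predictions Named vector, slide id -> predicted group (`PFI_S`/
#'   `PFI_L` or `Short`/`Long`).
#' @param outcomes Named vector, slide id -> actual group. Must cover
#'   exactly the same slides; a mismatch is an error listing the
#'   difference.
#' @return An object of class `metrics_report`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` (percent,
#'   full precision), `n_correct`, `n`.
#' @export
evaluate_predictions <- function(predictions, outcomes) {
  if (is.null(names(predictions)) || is.null(names(outcomes))) {
    stop("'predictions' and 'outcomes' must be named by slide id")
  }
  only_pred <- setdiff(names(predictions), names(outcomes))
  only_out <- setdiff(names(outcomes), names(predictions))
  if (length(only_pred) || length(only_out)) {
    stop("slide sets differ; only in predictions: {",
         paste(only_pred, collapse = ", "), "}, only in outcomes: {",
         paste(only_out, collapse = ", "), "}")
  }
  ids <- names(outcomes)
  pred <- as_pfi_group(unname(predictions[ids]))
  truth <- as_pfi_group(unname(outcomes[ids]))
  tp <- sum(pred == "PFI_S" & truth == "PFI_S")
  fp <- sum(pred == "PFI_S" & truth == "PFI_L")
  tn <- sum(pred == "PFI_L" & truth == "PFI_L")
  fn <- sum(pred == "PFI_L" & truth == "PFI_S")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         ppv = pct(tp, tp + fp),
         npv = pct(tn, tn + fn),
         accuracy = pct(tp + tn, length(ids)),
         n_correct = tp + tn, n = length(ids)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Confusion (positive = PFI_S): TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("Sensitivity %g%%  Specificity %g%%  PPV %g%%  NPV %g%%\n",
              round_half_up(x$sensitivity), round_half_up(x$specificity),
              round_half_up(x$ppv), round_half_up(x$npv)))
  cat(sprintf("Accuracy %g%% (%d/%d correct)\n",
              round_half_up(x$accuracy), x$n_correct, x$n))
  invisible(x)
}

#' Concordance between two replicate prediction sets
#'
#' Reports per-slide agreement between replicates, each replicate's
#' misclassified slides, and whether replicate 2's misclassified set is a
#' subset of replicate 1's.
#'
#' @param preds_rep1,preds_rep2 Named prediction vectors over the same
#'   slides.
#' @param outcomes Named actual-outcome vector over the same slides.
#' @return List: `agreement_pct`, `misclassified_rep1`,
#'   `misclassified_rep2`, `rep2_subset_of_rep1`.
#' @export
replicate_concordance <- function(preds_rep1, preds_rep2, outcomes) {
  ids <- names(outcomes)
  if (!setequal(ids, names(preds_rep1)) || !setequal(ids, names(preds_rep2))) {
    stop("replicate predictions and outcomes must cover the same slides")
  }
  p1 <- as_pfi_group(unname(preds_rep1[ids]))
  p2 <- as_pfi_group(unname(preds_rep2[ids]))
  truth <- as_pfi_group(unname(outcomes[ids]))
  mis1 <- sort(ids[p1 != truth])
  mis2 <- sort(ids[p2 != truth])
  list(agreement_pct = 100 * mean(p1 == p2),
       misclassified_rep1 = mis1,
       misclassified_rep2 = mis2,
       rep2_subset_of_rep1 = all(mis2 %in% mis1))
}

#' Evaluate the bundled fixture at a ratio cutoff
#'
#' Applies [classify_slides()] to the fixture's printed ratio column for one
#' replicate and scores the result against the actual outcomes.
#'
#' @param replicate 1 or 2.
#' @param cutoff Ratio cutoff (default 30).
#' @return List: `scores` (classified table), `metrics`
#'   (`metrics_report`).
#' @export
evaluate_table3 <- function(replicate = 2, cutoff = 30) {
  tab <- load_table3()
  tab <- tab[tab$replicate == replicate, ]
  cls <- classify_slides(tab, cutoff = cutoff)
  metrics <- evaluate_predictions(
    stats::setNames(cls$prediction, cls$slide_id),
    stats::setNames(as_pfi_group(cls$outcome), cls$slide_id)
  )
  list(scores = cls, metrics = metrics)
}
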