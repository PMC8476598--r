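# Patch-learner contract shared by all three stages.
#
# The original workflow ran a proprietary cloud CNN; the contribution being
# exercised here is the three-stage workflow, not the architecture, so the
# learner is a pluggable contract over patch features: fit(features, labels,
# seed) and predict_confidence(features) -> per-class confidences in [0, 1]
# summing to 1 per row. Backends:
#   "lda"    - linear discriminant (MASS); deterministic, extrapolates to
#              near-certain confidence away from the class boundary, which
#              is what the high-confidence biomarker filter needs.
#   "qda"    - quadratic discriminant (MASS).
#   "forest" - probability random forest (ranger); handles classes that are
#              not linearly separable in feature space (e.g. tumor textures
#              sitting between bright background/necrosis and dark folds).
#   "nnet"   - small single-hidden-layer neural network (nnet).

#' Create an (unfitted) patch learner
#'
#' @param backend One of `"lda"`, `"qda"`, `"forest"`, `"nnet"`.
#' @param params Backend options: `num_trees` (forest, default 100),
#'   `hidden` and `decay` (nnet, defaults 6 and 0.01).
#' @return An object of class `patch_learner`.
#' @export
patch_learner <- function(backend = c("lda", "qda", "forest", "nnet"),
                          params = list()) {
  backend <- match.arg(backend)
  structure(list(backend = backend, params = params, fit = NULL,
                 levels = NULL, center = NULL, scale = NULL, log = NULL),
            class = "patch_learner")
}

#' Fit a patch learner
#'
#' Deterministic given `(features, labels, params, seed)`; the seed drives
#' any backend randomness (forest bootstraps, network initialisation).
#' Features are standardised internally.
#'
#' @param learner A `patch_learner`.
#' @param features Numeric feature matrix (rows = patches).
#' @param labels Class labels (coerced to factor); at least two classes
#'   must be present.
#' @param seed Integer seed.
#' @return The fitted learner, with a `log` element (training summary).
#' @export
fit_patch_learner <- function(learner, features, labels, seed = 1) {
  stopifnot(inherits(learner, "patch_learner"))
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    stop("single-class training data: only '", levels(y), "' present")
  }
  if (nrow(features) != length(y)) stop("features/labels length mismatch")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl < 1e-9] <- 1
  x <- scale(features, center = ctr, scale = scl)
  p <- learner$params
  fit <- switch(learner$backend,
    lda = MASS::lda(x, grouping = y),
    qda = MASS::qda(x, grouping = y),
    forest = ranger::ranger(
      x = as.data.frame(x), y = y, probability = TRUE,
      num.trees = p$num_trees %||% 100L,
      seed = derive_seed(seed, "forest"), num.threads = 1L
    ),
    nnet = with_seed(seed, "nnet", {
      nnet::nnet(x, class_ind(y), size = p$hidden %||% 6L,
                 decay = p$decay %||% 0.01, maxit = p$maxit %||% 200L,
                 softmax = TRUE, trace = FALSE)
    })
  )
  learner$fit <- fit
  learner$levels <- levels(y)
  learner$center <- ctr
  learner$scale <- scl
  learner$log <- training_log(learner, x, y)
  learner
}

`%||%` <- function(a, b) if (is.null(a)) b else a

class_ind <- function(y) {
  out <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  out[cbind(seq_along(y), as.integer(y))] <- 1
  out
}

training_log <- function(learner, x, y) {
  conf <- predict_confidence_std(learner, x)
  pred <- learner$levels[max.col(conf, ties.method = "first")]
  data.frame(backend = learner$backend, n = length(y),
             n_classes = nlevels(y),
             train_accuracy = mean(pred == as.character(y)))
}

#' Per-class confidences for new patches
#'
#' @param learner A fitted `patch_learner`.
#' @param features Feature matrix on the same columns used in fitting.
#' @return Matrix with one column per class (named by class level); rows are
#'   non-negative and sum to 1.
#' @export
predict_confidence <- function(learner, features) {
  if (is.null(learner$fit)) stop("learner has not been fitted")
  x <- scale(features, center = learner$center, scale = learner$scale)
  predict_confidence_std(learner, x)
}

predict_confidence_std <- function(learner, x) {
  out <- switch(learner$backend,
    lda = stats::predict(learner$fit, x)$posterior,
    qda = stats::predict(learner$fit, x)$posterior,
    forest = stats::predict(learner$fit, data = as.data.frame(x),
                            num.threads = 1L)$predictions,
    nnet = stats::predict(learner$fit, x)
  )
  out <- as.matrix(out)
  out <- out[, learner$levels, drop = FALSE]
  out <- pmax(out, 0)
  sweep(out, 1, pmax(rowSums(out), 1e-12), "/")
}

# Subsample class indices so every class has the minority count; returns
# kept row indices in stable order. Seeded for reproducibility.
balance_classes <- function(labels, seed, key = "balance") {
  y <- factor(labels)
  n_min <- min(table(y))
  keep <- with_seed(seed, key, {
    unlist(lapply(levels(y), function(lv) {
      i <- which(y == lv)
      if (length(i) > n_min) sort(sample(i, n_min)) else i
    }))
  })
  sort(keep)
}
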