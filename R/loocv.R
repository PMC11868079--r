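#' Confusion counts for two-class predictions
#'
#' Class 1 is the positive class: `tp` counts class-1 patterns predicted
#' class 1, `fn` class-1 predicted class 2, `tn`/`fp` the mirrors.
#'
#' @param truth,predicted integer vectors coded in \{1, 2\}.
#' @param positive which code is the positive class (default 1).
#' @return List of class `"mml_confusion"` with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, predicted, positive = 1L) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("shape error: truth and predicted lengths differ")
  }
  pos <- truth == positive
  structure(
    list(tp = sum(pos & predicted == positive),
         fn = sum(pos & predicted != positive),
         tn = sum(!pos & predicted != positive),
         fp = sum(!pos & predicted == positive)),
    class = "mml_confusion"
  )
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, `(tp/(tp+fn) + tn/(tn+fp)) / 2`,
#' which weights both classes equally regardless of the imbalance ratio. A
#' constant predictor scores exactly 0.5.
#'
#' @param counts an [confusion_counts()] object (or a list with `tp`, `fn`,
#'   `tn`, `fp`).
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(counts) {
  n1 <- counts$tp + counts$fn
  n2 <- counts$tn + counts$fp
  if (n1 == 0L || n2 == 0L) {
    stop("undefined metric: a class has no patterns")
  }
  (counts$tp / n1 + counts$tn / n2) / 2
}

#' F1 score
#'
#' Harmonic mean of precision and recall for the positive class,
#' `2 tp / (2 tp + fp + fn)`; defined as 0 when `tp = 0` with errors
#' present.
#'
#' @inheritParams balanced_accuracy
#' @return Scalar in \[0, 1\].
#' @export
f1_score <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0L) {
    stop("undefined metric: no positive patterns or predictions")
  }
  2 * counts$tp / denom
}

#' @export
print.mml_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("class 1", "class 2"),
                              truth = c("class 1", "class 2")))
  print(m)
  invisible(x)
}

#' Leave-one-out cross-validation of the N-spherical classifier
#'
#' Deterministic evaluation: each pattern is held out in turn; the training
#' fold alone drives every learning computation, including the column-mean
#' imputation of missing values (fitted on the fold, applied to the held-out
#' pattern -- no leakage). Hyperparameters are either fixed (`att`, `bound`)
#' or self-adjusted by differential evolution: `mode = "per_fold"` retunes
#' inside every fold (the default, fully nested), `mode = "global"` tunes
#' once on the complete data and reuses the setting in every fold -- faster
#' but optimistic, since the held-out pattern influenced the tuning.
#'
#' @param x an [mml_data] object or numeric matrix (may contain `NA`).
#' @param y labels when `x` is a matrix.
#' @param att,bound fixed hyperparameters; both `NULL` to self-adjust.
#' @param control a [de_control()] configuration for self-adjustment.
#' @param mode `"per_fold"` or `"global"` retuning (self-adjustment only).
#' @param seed integer seed; fold f of a per-fold retune uses `seed + f - 1`.
#' @param positive label coded as class 1 when `x` is a matrix.
#' @return An object of class `"mml_loocv"`: `confusion`,
#'   `balanced_accuracy`, `f1`, and `per_fold` (data frame with columns
#'   `fold`, `true_class`, `predicted_class`, `att`, `bound`, `c1_in`).
#' @examples
#' d <- radial_shells(n1 = 8, n2 = 8, noise_dims = 5, seed = 7)
#' mml_loocv(d, att = 8, bound = 3)
#' @export
mml_loocv <- function(x, y = NULL, att = NULL, bound = NULL,
                      control = de_control(), mode = c("per_fold", "global"),
                      seed = 1L, positive = NULL) {
  mode <- match.arg(mode)
  d <- if (inherits(x, "mml_data")) x else mml_data(x, y, positive = positive)
  N <- nrow(d$x)
  if (N < 3L) stop("LOOCV needs at least 3 patterns")
  if (tabulate(d$y, 2L)[1L] < 2L || tabulate(d$y, 2L)[2L] < 2L) {
    stop("degenerate fold: every training fold must keep both classes; ",
         "each class needs at least 2 patterns")
  }
  fixed <- !is.null(att) && !is.null(bound)

  global_att <- att
  global_bound <- bound
  if (!fixed && mode == "global") {
    full <- d$x
    if (anyNA(full)) full <- impute_apply(full, impute_fit(full))
    tn <- mml_tune(mml_data(full, d$class_names[d$y],
                            positive = d$class_names[1L]),
                   control = control, seed = seed)
    global_att <- tn$best$att
    global_bound <- tn$best$bound
  }

  per_fold <- data.frame(fold = seq_len(N), true_class = d$y,
                         predicted_class = NA_integer_, att = NA_integer_,
                         bound = NA_integer_, c1_in = NA)
  for (f in seq_len(N)) {
    x_tr <- d$x[-f, , drop = FALSE]
    y_tr <- d$y[-f]
    if (length(unique(y_tr)) < 2L) {
      stop("degenerate fold ", f, ": training fold lost a class")
    }
    mu <- impute_fit(x_tr)
    x_tr <- impute_apply(x_tr, mu)
    x_te <- impute_apply(d$x[f, , drop = FALSE], mu)
    if (fixed || mode == "global") {
      lp <- suppressWarnings(
        learn_phase(x_tr, y_tr,
                    if (fixed) att else global_att,
                    if (fixed) bound else global_bound)
      )
    } else {
      fold_data <- mml_data(x_tr, c("1", "2")[y_tr], positive = "1")
      tn <- mml_tune(fold_data, control = control, seed = seed + f - 1L)
      lp <- suppressWarnings(
        learn_phase(x_tr, y_tr, tn$best$att, tn$best$bound)
      )
    }
    proj <- project_pattern(x_te[1L, ], lp$learning_attributes)
    vt <- vote_and_classify(progressive_norms(proj), lp$boundaries, lp$c1_in)
    per_fold$predicted_class[f] <- vt$predicted
    per_fold$att[f] <- lp$att
    per_fold$bound[f] <- lp$bound
    per_fold$c1_in[f] <- lp$c1_in
  }
  conf <- confusion_counts(per_fold$true_class, per_fold$predicted_class)
  structure(
    list(confusion = conf,
         balanced_accuracy = balanced_accuracy(conf),
         f1 = f1_score(conf),
         per_fold = per_fold,
         class_names = d$class_names,
         mode = if (fixed) "fixed" else mode),
    class = "mml_loocv"
  )
}

#' @export
print.mml_loocv <- function(x, digits = 4L, ...) {
  cat("Leave-one-out cross-validation (", nrow(x$per_fold), " folds, ",
      x$mode, " hyperparameters)\n", sep = "")
  cat(sprintf("  balanced accuracy: %.*f\n", digits, x$balanced_accuracy))
  cat(sprintf("  F1 (positive = '%s'): %.*f\n", x$class_names[1L], digits,
              x$f1))
  cat(sprintf("  confusion: tp=%d fn=%d tn=%d fp=%d\n", x$confusion$tp,
              x$confusion$fn, x$confusion$tn, x$confusion$fp))
  invisible(x)
}
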