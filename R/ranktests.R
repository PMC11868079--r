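#' Midranks of one score row
#'
#' Rank 1 goes to the best value; tied values share the average of the rank
#' positions they occupy, so every row of ranks sums to `k (k + 1) / 2`.
#'
#' @param row numeric vector of scores for one dataset across algorithms.
#' @param higher_is_better `TRUE` when larger scores are better (the case
#'   for balanced accuracy).
#' @return Numeric vector of midranks.
#' @examples
#' midranks(c(0.8636, 1, 0.9359, 0.9359, 1, 1, 1))
#' @export
midranks <- function(row, higher_is_better = TRUE) {
  if (any(!is.finite(row))) stop("scores must be finite")
  rank(if (higher_is_better) -row else row, ties.method = "average")
}

#' Friedman mean-rank test over a score matrix
#'
#' Ranks the algorithms within every dataset with [midranks()], averages the
#' ranks per algorithm and computes the classic chi-square Friedman statistic
#' `12 / (N k (k+1)) * sum(Rj^2) - 3 N (k+1)` on the rank sums `Rj`, with a
#' p-value from the chi-square distribution with `k - 1` degrees of freedom
#' (no Iman-Davenport correction).
#'
#' @param scores numeric matrix, datasets in rows, algorithms in columns
#'   (with dimnames where available), or the result of
#'   [read_score_matrix()].
#' @param higher_is_better passed to [midranks()].
#' @return An object of class `"mml_friedman"`: `rank_matrix`, `mean_ranks`,
#'   `chi_square`, `p_value`, `n_datasets`, `n_algorithms`.
#' @export
friedman_ranks <- function(scores, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  k <- ncol(scores)
  if (N < 2L || k < 2L) {
    stop("configuration error: need at least 2 datasets and 2 algorithms")
  }
  if (anyNA(scores)) stop("scores must have no missing entries")
  R <- t(apply(scores, 1L, midranks, higher_is_better = higher_is_better))
  colnames(R) <- colnames(scores)
  Rj <- colSums(R)
  chi2 <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  structure(
    list(rank_matrix = R,
         mean_ranks = colMeans(R),
         chi_square = chi2,
         p_value = stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE),
         n_datasets = N,
         n_algorithms = k),
    class = "mml_friedman"
  )
}

#' @export
print.mml_friedman <- function(x, digits = 4L, ...) {
  cat("Friedman mean-rank test:", x$n_datasets, "datasets x",
      x$n_algorithms, "algorithms\n")
  mr <- sort(x$mean_ranks)
  for (i in seq_along(mr)) {
    cat(sprintf("  %-14s %.*f\n", names(mr)[i], digits, mr[i]))
  }
  cat(sprintf("chi-square = %.4f (df = %d), p = %.3g\n", x$chi_square,
              x$n_algorithms - 1L, x$p_value))
  invisible(x)
}

#' Holm step-down post-hoc comparison against a control
#'
#' Compares every algorithm with the control (by default the best mean rank)
#' through `z = |R_control - R_i| / SE` with `SE = sqrt(k (k+1) / (6 N))`,
#' two-sided normal p-values, comparisons sorted by descending z, and
#' step-down thresholds `alpha / (k - i)` for the i-th sorted comparison.
#' Rejection stops at the first comparison whose p-value exceeds its
#' threshold.
#'
#' @param fr an [friedman_ranks()] result.
#' @param alpha family-wise significance level.
#' @param control algorithm name or column index, or `NULL` for the best
#'   mean rank.
#' @return An object of class `"mml_holm"`: a data frame `comparisons` with
#'   columns `algorithm`, `z`, `p`, `threshold`, `rejected`, plus `control`,
#'   `se`, `alpha`.
#' @export
holm_posthoc <- function(fr, alpha = 0.05, control = NULL) {
  if (!inherits(fr, "mml_friedman")) {
    stop("'fr' must be a friedman_ranks() result")
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  mr <- fr$mean_ranks
  k <- fr$n_algorithms
  N <- fr$n_datasets
  nm <- names(mr)
  if (is.null(nm)) nm <- paste0("alg", seq_len(k))
  if (is.null(control)) {
    ci <- which.min(mr)
  } else if (is.character(control)) {
    ci <- match(control, nm)
    if (is.na(ci)) stop("control '", control, "' not among the algorithms")
  } else {
    ci <- as.integer(control)
    if (ci < 1L || ci > k) stop("control index out of range")
  }
  se <- sqrt(k * (k + 1) / (6 * N))
  others <- setdiff(seq_len(k), ci)
  z <- abs(mr[ci] - mr[others]) / se
  p <- 2 * stats::pnorm(-z)
  ord <- order(-z)
  comparisons <- data.frame(
    algorithm = nm[others][ord],
    z = unname(z[ord]),
    p = unname(p[ord]),
    threshold = alpha / (k - seq_along(ord)),
    stringsAsFactors = FALSE
  )
  # step-down: reject until the first comparison fails its threshold
  rejected <- logical(nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    if (comparisons$p[i] <= comparisons$threshold[i]) {
      rejected[i] <- TRUE
    } else {
      break
    }
  }
  comparisons$rejected <- rejected
  structure(
    list(comparisons = comparisons, control = nm[ci], se = se, alpha = alpha),
    class = "mml_holm"
  )
}

#' @export
print.mml_holm <- function(x, ...) {
  cat("Holm post-hoc, control =", x$control,
      sprintf("(SE = %.6f, alpha = %g)\n", x$se, x$alpha))
  tab <- x$comparisons
  tab$z <- sprintf("%.6f", tab$z)
  tab$p <- sprintf("%.6g", tab$p)
  tab$threshold <- sprintf("%.6g", tab$threshold)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' First-place counts per algorithm
#'
#' For each algorithm, the number of datasets where its score equals the row
#' optimum; ties count for every tied algorithm.
#'
#' @inheritParams friedman_ranks
#' @return Named integer vector.
#' @export
first_place_counts <- function(scores, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  best <- if (higher_is_better) {
    apply(scores, 1L, max)
  } else {
    apply(scores, 1L, min)
  }
  counts <- colSums(scores == best)
  stats::setNames(as.integer(counts), colnames(scores))
}

#' Read a datasets-by-algorithms score matrix from CSV
#'
#' Expects a header row of algorithm names and a first column of dataset
#' names. Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @return Numeric matrix with dataset rownames and algorithm colnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("score matrix has non-numeric entries in ", path)
  rownames(m) <- df[[1L]]
  m
}
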