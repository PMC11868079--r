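#' Construct a labelled two-class dataset
#'
#' The container all fitting and evaluation functions work on: a numeric
#' pattern matrix together with class labels coded to the integers 1 and 2.
#' Class 1 is the positive class (inside/outside orientation, F1, confusion
#' layout all treat it as positive). Labels may be given as any two-valued
#' vector; `positive` selects which original label becomes class 1, the
#' default being the lexicographically first label.
#'
#' @param x numeric matrix or data frame, patterns in rows, attributes in
#'   columns. Missing entries (`NA`) are allowed; they are imputed fold-wise
#'   during evaluation, or must be imputed before fitting.
#' @param y vector of class labels, one per row of `x`, with exactly two
#'   distinct values.
#' @param positive the label to code as class 1, or `NULL` for the
#'   lexicographically first.
#' @param attribute_names optional column identifiers; defaults to
#'   `colnames(x)` then `V1..VL`.
#' @return An object of class `"mml_data"`: list with `x` (numeric matrix),
#'   `y` (integer vector in \{1, 2\}), `class_names` (character of length 2,
#'   original labels for classes 1 and 2), `attribute_names`.
#' @examples
#' d <- mml_data(matrix(rnorm(20), 10, 2), rep(c("case", "control"), 5),
#'               positive = "case")
#' table(d$y)
#' @export
mml_data <- function(x, y, positive = NULL, attribute_names = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("'x' must be numeric")
  }
  if (length(y) != nrow(x)) {
    stop("length of 'y' (", length(y), ") does not match rows of 'x' (",
         nrow(x), ")")
  }
  coded <- code_labels(y, positive)
  if (is.null(attribute_names)) {
    attribute_names <- colnames(x)
  }
  if (is.null(attribute_names)) {
    attribute_names <- paste0("V", seq_len(ncol(x)))
  }
  colnames(x) <- attribute_names
  structure(
    list(x = x, y = coded$y, class_names = coded$class_names,
         attribute_names = attribute_names),
    class = "mml_data"
  )
}

# Map a two-valued label vector to integer codes {1, 2}.
code_labels <- function(y, positive = NULL) {
  if (is.factor(y)) y <- as.character(y)
  lev <- sort(unique(as.character(y)))
  if (length(lev) > 2L) {
    stop("unsupported multiclass input: found ", length(lev),
         " distinct labels (", paste(utils::head(lev, 4), collapse = ", "),
         "...); only binary classification is supported")
  }
  if (length(lev) < 2L) {
    stop("degenerate training data: only one class present ('", lev, "')")
  }
  if (!is.null(positive)) {
    positive <- as.character(positive)
    if (!positive %in% lev) {
      stop("positive class '", positive, "' not among the labels: ",
           paste(lev, collapse = ", "))
    }
    lev <- c(positive, setdiff(lev, positive))
  }
  list(y = ifelse(as.character(y) == lev[1L], 1L, 2L), class_names = lev)
}

#' @export
print.mml_data <- function(x, ...) {
  cat("Two-class dataset:", nrow(x$x), "patterns x", ncol(x$x), "attributes\n")
  n <- tabulate(x$y, 2L)
  cat(sprintf("  class 1 '%s': %d patterns\n", x$class_names[1L], n[1L]))
  cat(sprintf("  class 2 '%s': %d patterns\n", x$class_names[2L], n[2L]))
  if (anyNA(x$x)) {
    cat("  missing cells:", sum(is.na(x$x)), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mml_data <- function(x, ...) {
  df <- as.data.frame(x$x)
  df$class <- x$class_names[x$y]
  df
}

#' Split a dataset into its two class matrices
#'
#' First step of the learning phase: partition the training patterns into the
#' class-1 matrix `Y1` and the class-2 matrix `Y2`, preserving row order
#' within each class.
#'
#' @param data an [mml_data] object, or a numeric matrix when `y` is given.
#' @param y integer labels in \{1, 2\} (ignored when `data` is an
#'   [mml_data]).
#' @return List with numeric matrices `Y1` and `Y2`.
#' @export
split_by_class <- function(data, y = NULL) {
  if (inherits(data, "mml_data")) {
    x <- data$x
    y <- data$y
  } else {
    x <- as.matrix(data)
  }
  if (is.null(y)) stop("labels 'y' are required")
  y <- as.integer(y)
  if (!all(y %in% c(1L, 2L))) {
    stop("labels must be coded 1 or 2; see mml_data()")
  }
  n1 <- sum(y == 1L)
  n2 <- sum(y == 2L)
  if (n1 < 1L || n2 < 1L) {
    stop("degenerate training data: class ", if (n1 < 1L) 1L else 2L,
         " has no patterns")
  }
  list(Y1 = x[y == 1L, , drop = FALSE], Y2 = x[y == 2L, , drop = FALSE])
}

# Column-mean imputation fitted on training rows only, applied to any matrix.
# Columns that are entirely missing in the training rows impute to 0.
impute_fit <- function(x_train) {
  mu <- colMeans(x_train, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  mu
}

impute_apply <- function(x, mu) {
  if (!anyNA(x)) return(x)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2L]]
  x
}
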