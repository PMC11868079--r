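#' T-means thresholds per attribute
#'
#' For every attribute the threshold is the midpoint of the two class means:
#' `T[j] = (mean(Y1[, j]) + mean(Y2[, j])) / 2`. This "twice mean" threshold
#' is the univariate separator the attribute ranking is scored against.
#'
#' @param Y1,Y2 numeric matrices with the class-1 and class-2 training
#'   patterns, equal column counts.
#' @return List with numeric vectors `m1`, `m2` (class column means) and
#'   `t_means` (their midpoints), one entry per attribute.
#' @export
t_means <- function(Y1, Y2) {
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  if (nrow(Y1) == 0L || nrow(Y2) == 0L) {
    stop("degenerate training data: a class matrix is empty")
  }
  if (ncol(Y1) != ncol(Y2)) {
    stop("shape error: Y1 has ", ncol(Y1), " columns but Y2 has ", ncol(Y2))
  }
  m1 <- colMeans(Y1)
  m2 <- colMeans(Y2)
  list(m1 = m1, m2 = m2, t_means = (m1 + m2) / 2)
}

#' Univariate error counts under the two class orientations
#'
#' `e1[j]` counts the errors committed assuming class 1 lies below the
#' T-means threshold of attribute j: class-1 values strictly above plus
#' class-2 values strictly below. `e2[j]` is the mirror (class 1 assumed
#' above). Values exactly equal to the threshold are errors in neither
#' orientation.
#'
#' @param Y1,Y2 class matrices as in [t_means()].
#' @param t_means numeric vector of thresholds, one per attribute (the
#'   `t_means` element of [t_means()]).
#' @return List with integer vectors `e1` and `e2`.
#' @export
error_vectors <- function(Y1, Y2, t_means) {
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  if (length(t_means) != ncol(Y1) || ncol(Y1) != ncol(Y2)) {
    stop("shape error: thresholds (", length(t_means),
         ") and columns (", ncol(Y1), ", ", ncol(Y2), ") disagree")
  }
  above1 <- colSums(sweep(Y1, 2L, t_means, ">"))
  below1 <- colSums(sweep(Y1, 2L, t_means, "<"))
  above2 <- colSums(sweep(Y2, 2L, t_means, ">"))
  below2 <- colSums(sweep(Y2, 2L, t_means, "<"))
  list(e1 = as.integer(above1 + below2), e2 = as.integer(below1 + above2))
}

#' Class-1 orientation criterion
#'
#' Decides whether class 1 is modelled as lying inside the spherical
#' frontier: `TRUE` iff `mean(e1) < mean(e2)` strictly; a tie yields `FALSE`.
#' When `TRUE` the attribute ranking uses `e1` and class 1 is assigned inside
#' the boundaries; when `FALSE` the mirror holds.
#'
#' @param e1,e2 integer error vectors from [error_vectors()].
#' @return Logical scalar (the `C1_IN` flag).
#' @export
orientation <- function(e1, e2) {
  if (length(e1) != length(e2) || length(e1) < 1L) {
    stop("shape error: e1 and e2 must have equal positive length")
  }
  mean(e1) < mean(e2)
}

#' Rank attributes by ascending error count
#'
#' Stable sort: ties are broken by ascending attribute index. The ranking is
#' truncated to the first `att` attributes; `att` larger than the number of
#' attributes is clamped with a warning (this keeps the metaheuristic loop
#' total when a proposal overshoots).
#'
#' @param errors integer vector of per-attribute error counts.
#' @param att number of attributes to retain (1-based count).
#' @return List with `ordered_indices` (1-based attribute indices) and
#'   `ordered_errors` (matching non-decreasing counts).
#' @export
rank_attributes <- function(errors, att) {
  L <- length(errors)
  if (att < 1L) stop("'att' must be at least 1")
  if (att > L) {
    warning("'att' (", att, ") exceeds the number of attributes (", L,
            "); clamped")
    att <- L
  }
  ord <- order(errors, seq_len(L))[seq_len(att)]
  list(ordered_indices = ord, ordered_errors = as.integer(errors[ord]))
}

#' Spherical frontier between two sets of radial norms
#'
#' The decision radius is the midpoint of the adjacent class extremes: with
#' class 1 inside (`c1_in = TRUE`) it is `(max(r1) + min(r2)) / 2`, otherwise
#' `(min(r1) + max(r2)) / 2`.
#'
#' @param r1,r2 non-empty numeric vectors of per-pattern radial norms for
#'   classes 1 and 2.
#' @param c1_in logical orientation flag from [orientation()].
#' @return Non-negative scalar boundary radius.
#' @export
attribute_radius <- function(r1, r2, c1_in) {
  if (length(r1) == 0L || length(r2) == 0L) {
    stop("degenerate training data: empty radius vector for a class")
  }
  if (isTRUE(c1_in)) (max(r1) + min(r2)) / 2 else (min(r1) + max(r2)) / 2
}

#' Resubstitution errors at a spherical boundary
#'
#' With class 1 inside, errors are class-1 radii strictly outside the
#' boundary plus class-2 radii strictly inside; with class 1 outside, the
#' mirror. Radii exactly on the boundary are not errors.
#'
#' @param r1,r2 numeric vectors of radial norms.
#' @param boundary finite boundary radius.
#' @param c1_in logical orientation flag.
#' @return Non-negative integer error count.
#' @export
boundary_errors <- function(r1, r2, boundary, c1_in) {
  if (!is.finite(boundary)) stop("'boundary' must be finite")
  if (isTRUE(c1_in)) {
    sum(r1 > boundary) + sum(r2 < boundary)
  } else {
    sum(r1 < boundary) + sum(r2 > boundary)
  }
}

#' Progressive spherical boundaries over nested attribute sets
#'
#' For k = 1..bound the radial norms of every training pattern over the first
#' k (re-ranked) attributes are computed; the k-th boundary is the
#' [attribute_radius()] of those norms and the k-th per-set error the
#' [boundary_errors()] count at it. Because the norms are prefix norms they
#' are non-decreasing in k for every pattern.
#'
#' @param Y1sel,Y2sel class matrices whose columns are the selected
#'   attributes in final rank order.
#' @param bound number of progressive sets (clamped to the available
#'   attribute count with a warning).
#' @param c1_in logical orientation flag.
#' @return List with numeric `boundaries` and integer `per_set_errors`, both
#'   of length `bound`.
#' @export
progressive_boundaries <- function(Y1sel, Y2sel, bound, c1_in) {
  Y1sel <- as.matrix(Y1sel)
  Y2sel <- as.matrix(Y2sel)
  k_max <- ncol(Y1sel)
  if (bound < 1L) stop("'bound' must be at least 1")
  if (bound > k_max) {
    warning("'bound' (", bound, ") exceeds the selected attributes (", k_max,
            "); clamped")
    bound <- k_max
  }
  boundaries <- numeric(bound)
  per_set_errors <- integer(bound)
  s1 <- numeric(nrow(Y1sel))
  s2 <- numeric(nrow(Y2sel))
  for (k in seq_len(bound)) {
    s1 <- s1 + Y1sel[, k]^2
    s2 <- s2 + Y2sel[, k]^2
    r1 <- sqrt(s1)
    r2 <- sqrt(s2)
    boundaries[k] <- attribute_radius(r1, r2, c1_in)
    per_set_errors[k] <- boundary_errors(r1, r2, boundaries[k], c1_in)
  }
  list(boundaries = boundaries, per_set_errors = per_set_errors)
}

# The full learning phase on coded data. Internal workhorse behind mml().
learn_phase <- function(x, y, att, bound, att_percent = FALSE) {
  sp <- split_by_class(x, y)
  L <- ncol(sp$Y1)
  if (L < 1L) stop("degenerate training data: no attributes")
  if (att_percent) {
    att <- max(1L, as.integer(round(att * L / 100)))
  }
  att <- as.integer(att)
  bound <- as.integer(bound)
  if (att < 1L || bound < 1L) stop("'att' and 'bound' must be at least 1")
  if (bound > att) {
    warning("'bound' (", bound, ") exceeds 'att' (", att, "); clamped")
    bound <- att
  }
  tm <- t_means(sp$Y1, sp$Y2)
  ev <- error_vectors(sp$Y1, sp$Y2, tm$t_means)
  c1_in <- orientation(ev$e1, ev$e2)
  # stage 1: rank all attributes by the orientation's univariate errors
  stage1 <- rank_attributes(if (c1_in) ev$e1 else ev$e2, att)
  cand <- stage1$ordered_indices
  # stage 2: score each candidate by its single-attribute spherical frontier
  att_errors <- integer(length(cand))
  att_radii <- numeric(length(cand))
  for (i in seq_along(cand)) {
    r1 <- abs(sp$Y1[, cand[i]])
    r2 <- abs(sp$Y2[, cand[i]])
    att_radii[i] <- attribute_radius(r1, r2, c1_in)
    att_errors[i] <- boundary_errors(r1, r2, att_radii[i], c1_in)
  }
  # re-rank candidates by radial error, stable in candidate (stage-1) order
  ord <- order(att_errors, seq_along(cand))
  sel <- cand[ord][seq_len(bound)]
  prog <- progressive_boundaries(sp$Y1[, sel, drop = FALSE],
                                 sp$Y2[, sel, drop = FALSE],
                                 bound, c1_in)
  list(
    c1_in = c1_in,
    learning_attributes = sel,
    boundaries = prog$boundaries,
    per_set_errors = prog$per_set_errors,
    att = att,
    bound = bound,
    training_error = min(prog$per_set_errors),
    t_means = tm$t_means,
    e1 = ev$e1,
    e2 = ev$e2,
    candidates = cand,
    candidate_radii = att_radii,
    candidate_errors = att_errors
  )
}

#' Fit the N-spherical minimalist classifier
#'
#' Learns a two-class model in four steps: (1) per-attribute T-means
#' thresholds and the univariate error vectors `e1`/`e2`; (2) the orientation
#' criterion `c1_in = mean(e1) < mean(e2)` deciding whether class 1 lies
#' inside the spherical frontier; (3) two-stage attribute ranking -- the
#' `att` best attributes by univariate errors, re-ranked by the
#' resubstitution error of each attribute's own spherical frontier; (4)
#' progressive spherical boundaries over the first `bound` re-ranked
#' attributes. The training error is the minimum resubstitution error over
#' the progressive boundary sets, which is also the fitness the
#' differential-evolution tuner minimises.
#'
#' When `att` or `bound` is `NULL` the two hyperparameters are self-adjusted
#' by differential evolution (see [mml_tune()] and [de_control()]).
#'
#' @param x an [mml_data] object, a numeric matrix (patterns x attributes),
#'   or a formula.
#' @param ... further arguments passed between methods.
#' @return An object of class `"mml"`. Components include `c1_in`,
#'   `learning_attributes` (1-based indices in final rank order),
#'   `boundaries`, `per_set_errors`, `att`, `bound`, `training_error`,
#'   `class_names`, and when tuned, `tuning` (the [mml_tune()] trace).
#' @examples
#' d <- radial_shells(n1 = 15, n2 = 15, informative_dims = 3,
#'                    noise_dims = 10, seed = 7)
#' fit <- mml(d, att = ncol(d$x), bound = 3)
#' fit
#' predict(fit, d$x[1:3, ])
#' @export
mml <- function(x, ...) UseMethod("mml")

#' @rdname mml
#' @param y class labels (two distinct values) when `x` is a matrix.
#' @param att number of candidate attributes retained after the univariate
#'   ranking, or `NULL` to self-adjust.
#' @param bound number of progressive boundary sets (votes), `<= att`, or
#'   `NULL` to self-adjust.
#' @param positive label to treat as class 1 (see [mml_data()]).
#' @param att_percent interpret `att` as a percentage of the attribute count
#'   instead of an absolute count.
#' @param control a [de_control()] configuration for self-adjustment.
#' @param seed integer seed for the self-adjustment search.
#' @export
mml.default <- function(x, y, att = NULL, bound = NULL, positive = NULL,
                        att_percent = FALSE, control = de_control(),
                        seed = NULL, ...) {
  d <- if (inherits(x, "mml_data")) x else mml_data(x, y, positive = positive)
  if (anyNA(d$x)) {
    stop("missing values in 'x'; impute first (mml_loocv() imputes fold-wise)")
  }
  if (is.null(att) || is.null(bound)) {
    tune <- mml_tune(d, control = control, seed = seed)
    fit <- tune$model
    fit$tuning <- tune
    fit$call <- match.call()
    return(fit)
  }
  lp <- learn_phase(d$x, d$y, att, bound, att_percent = att_percent)
  new_mml(lp, d, match.call())
}

#' @rdname mml
#' @export
mml.mml_data <- function(x, att = NULL, bound = NULL, ...) {
  mml.default(x, y = NULL, att = att, bound = bound, ...)
}

#' @rdname mml
#' @param formula a formula such as `class ~ .` naming the label column.
#' @param data a data frame holding the attributes and the label column.
#' @export
mml.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tt <- attr(mf, "terms")
  xm <- stats::model.matrix(tt, mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  fit <- mml.default(xm, y, ...)
  fit$terms <- tt
  fit$call <- match.call()
  fit
}

# assemble the S3 model object from a learn_phase() result
new_mml <- function(lp, d, call) {
  structure(
    list(
      c1_in = lp$c1_in,
      learning_attributes = lp$learning_attributes,
      boundaries = lp$boundaries,
      per_set_errors = lp$per_set_errors,
      att = lp$att,
      bound = lp$bound,
      training_error = lp$training_error,
      candidates = lp$candidates,
      candidate_radii = lp$candidate_radii,
      candidate_errors = lp$candidate_errors,
      class_names = d$class_names,
      attribute_names = d$attribute_names,
      n_attributes = ncol(d$x),
      n1 = sum(d$y == 1L),
      n2 = sum(d$y == 2L),
      call = call
    ),
    class = "mml"
  )
}

#' @export
print.mml <- function(x, digits = 4L, ...) {
  cat("N-spherical minimalist classifier\n")
  if (!is.null(x$call)) {
    cat("Call: ", deparse(x$call), "\n", sep = "")
  }
  cat(sprintf("Class 1 ('%s') lies %s the spherical boundaries (c1_in = %s)\n",
              x$class_names[1L], if (x$c1_in) "inside" else "outside",
              if (x$c1_in) "1" else "0"))
  cat("Learning attributes:",
      paste(x$attribute_names[x$learning_attributes], collapse = ", "), "\n")
  cat("Spherical boundaries:",
      paste(format(round(x$boundaries, digits), nsmall = digits),
            collapse = ", "), "\n")
  cat(sprintf("att = %d, bound = %d, training error = %d (of %d patterns)\n",
              x$att, x$bound, x$training_error, x$n1 + x$n2))
  invisible(x)
}

#' @export
summary.mml <- function(object, ...) {
  structure(list(model = object), class = "summary.mml")
}

#' @export
print.summary.mml <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nCandidate attributes (final rank order):\n")
  ord <- order(m$candidate_errors, seq_along(m$candidates))
  tab <- data.frame(
    attribute = m$attribute_names[m$candidates[ord]],
    radius = round(m$candidate_radii[ord], 4),
    errors = m$candidate_errors[ord]
  )
  print(utils::head(tab, 20), row.names = FALSE)
  if (nrow(tab) > 20) cat("  ... (", nrow(tab) - 20, " more)\n", sep = "")
  cat("\nProgressive sets: boundary / resubstitution errors\n")
  print(data.frame(k = seq_len(m$bound),
                   boundary = round(m$boundaries, 4),
                   errors = m$per_set_errors), row.names = FALSE)
  invisible(x)
}

#' @export
coef.mml <- function(object, ...) {
  stats::setNames(object$boundaries,
                  object$attribute_names[object$learning_attributes])
}
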