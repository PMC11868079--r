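#' Project a pattern onto the model's learning attributes
#'
#' Extracts the components of a pattern at the stored attribute indices, in
#' the stored order. Attributes outside the learning set never influence
#' classification.
#'
#' @param pattern numeric vector (a full-width pattern).
#' @param attributes integer vector of 1-based attribute indices.
#' @return Numeric vector of `length(attributes)`.
#' @export
project_pattern <- function(pattern, attributes) {
  if (max(attributes) > length(pattern) || min(attributes) < 1L) {
    stop("model/data mismatch: attribute index up to ", max(attributes),
         " requested but the pattern has ", length(pattern), " components")
  }
  as.numeric(pattern[attributes])
}

#' Vote over progressive spherical boundaries
#'
#' Vote k goes to class 1 iff the k-th progressive norm falls on class 1's
#' side of the k-th boundary: strictly inside when `c1_in` is `TRUE`,
#' strictly outside when `FALSE`. A norm exactly equal to its boundary votes
#' class 2. The pattern is assigned class 1 when class-1 votes reach at least
#' half the number of boundaries.
#'
#' @param norms numeric vector of progressive radial norms (see
#'   [progressive_norms()]).
#' @param boundaries numeric vector of spherical boundaries, same length.
#' @param c1_in logical orientation flag.
#' @return An object of class `"mml_votes"`: list with `norms`, `boundaries`,
#'   `votes` (logical, `TRUE` = class 1), `votes_class1`, and `predicted`
#'   (integer class code 1 or 2).
#' @examples
#' vote_and_classify(c(108, 438.5077, 909.6692, 944.7344, 962.2952),
#'                   c(49, 367.4421, 579.4759, 621.0160, 691.8988),
#'                   c1_in = FALSE)
#' @export
vote_and_classify <- function(norms, boundaries, c1_in) {
  if (length(norms) != length(boundaries) || length(norms) < 1L) {
    stop("model/data mismatch: ", length(norms), " norms vs ",
         length(boundaries), " boundaries")
  }
  votes <- if (isTRUE(c1_in)) norms < boundaries else norms > boundaries
  votes_class1 <- sum(votes)
  predicted <- if (votes_class1 >= length(votes) / 2) 1L else 2L
  structure(
    list(norms = norms, boundaries = boundaries, votes = votes,
         votes_class1 = votes_class1, predicted = predicted),
    class = "mml_votes"
  )
}

#' @export
print.mml_votes <- function(x, digits = 4L, ...) {
  tab <- data.frame(
    k = seq_along(x$norms),
    norm = round(x$norms, digits),
    boundary = round(x$boundaries, digits),
    vote = ifelse(x$votes, "class 1", "class 2")
  )
  print(tab, row.names = FALSE)
  cat(sprintf("votes for class 1: %d of %d -> predicted class %d\n",
              x$votes_class1, length(x$votes), x$predicted))
  invisible(x)
}

# classify one full-width pattern against a fitted model
classify_one <- function(model, pattern) {
  proj <- project_pattern(pattern, model$learning_attributes)
  vote_and_classify(progressive_norms(proj), model$boundaries, model$c1_in)
}

#' Predict method for N-spherical models
#'
#' Each pattern is projected onto the learning attributes, its progressive
#' radial norms are compared with the spherical boundaries, and the boundary
#' votes are tallied ([vote_and_classify()]). Classification is
#' deterministic.
#'
#' @param object a fitted [mml] model.
#' @param newdata numeric matrix or data frame of patterns (full attribute
#'   width), or a single pattern as a vector. For models fitted through the
#'   formula interface a data frame with the original columns.
#' @param type `"class"` for a factor of predicted labels, `"votes"` for the
#'   per-pattern class-1 vote count, `"trace"` for the full list of
#'   [vote_and_classify()] objects.
#' @param ... unused.
#' @return Factor, integer vector, or list according to `type`.
#' @export
predict.mml <- function(object, newdata,
                        type = c("class", "votes", "trace"), ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    newdata <- stats::model.matrix(tt, mf)
    newdata <- newdata[, colnames(newdata) != "(Intercept)", drop = FALSE]
  }
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  traces <- lapply(seq_len(nrow(newdata)),
                   function(i) classify_one(object, newdata[i, ]))
  switch(type,
    class = factor(object$class_names[vapply(traces, `[[`, 1L, "predicted")],
                   levels = object$class_names),
    votes = vapply(traces, `[[`, 1L, "votes_class1"),
    trace = traces
  )
}
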