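#' Radial norm of a numeric vector
#'
#' Euclidean distance of a point from the origin, the radial component of the
#' N-spherical coordinate system. This is the only geometric quantity the
#' classifier's decision path uses: patterns projected onto a progressive
#' attribute set are compared with a spherical boundary through their radial
#' norm alone.
#'
#' @param x numeric vector of length >= 1 with finite components.
#' @return A non-negative scalar, `sqrt(sum(x^2))`. For a single component
#'   this is the absolute value.
#' @examples
#' radial_norm(c(3, 4)) # 5
#' @seealso [cartesian_to_nspherical()], [progressive_norms()]
#' @export
radial_norm <- function(x) {
  x <- check_finite_vector(x, "x")
  sqrt(sum(x^2))
}

#' Cartesian to N-spherical coordinate transform
#'
#' Transforms a point with n Cartesian components into a radius plus n-1
#' angles. The k-th angle is `acos(x[k] / t[k])` where `t[k]` is the radial
#' norm of the tail `x[k:n]`. All angles therefore lie in `[0, pi]`; the sign
#' of the last component is not recoverable from the angles (a documented
#' limitation of the arccos form). When a tail norm is exactly zero the
#' corresponding angle is defined as 0 so the transform is total.
#'
#' @param x numeric vector of length >= 2 with finite components.
#' @return An object of class `"nspherical"`: a list with elements `radius`
#'   (non-negative scalar) and `angles` (numeric vector of length
#'   `length(x) - 1`, each in `[0, pi]`).
#' @examples
#' cartesian_to_nspherical(c(1, 0)) # radius 1, angle 0
#' cartesian_to_nspherical(c(0, 1)) # radius 1, angle pi/2
#' @export
cartesian_to_nspherical <- function(x) {
  x <- check_finite_vector(x, "x")
  n <- length(x)
  if (n < 2L) {
    stop("invalid input: 'x' must have at least 2 components, got ", n)
  }
  # tail norms t[k] = ||x[k:n]||, computed from the cumulative sum of squares
  tails <- sqrt(rev(cumsum(rev(x^2))))
  angles <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    if (tails[k] == 0) {
      angles[k] <- 0
    } else {
      # clamp against floating-point excursions outside [-1, 1]
      angles[k] <- acos(max(-1, min(1, x[k] / tails[k])))
    }
  }
  structure(list(radius = tails[1L], angles = angles), class = "nspherical")
}

#' @export
print.nspherical <- function(x, ...) {
  cat("N-spherical point\n")
  cat("  radius:", format(x$radius), "\n")
  cat("  angles (rad):", paste(format(x$angles, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Progressive radial norms of projection prefixes
#'
#' Entry k is the radial norm of the first k components, so the result is
#' non-decreasing. These are the "spherical norms" a test pattern presents to
#' the nested progressive boundary sets during classification.
#'
#' @param x numeric vector (a pattern projected onto the ordered learning
#'   attributes).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' progressive_norms(c(108, 425)) # 108.0000 438.5077
#' @export
progressive_norms <- function(x) {
  x <- check_finite_vector(x, "x")
  sqrt(cumsum(x^2))
}

# shared input check: numeric, non-empty, all finite; names the first bad index
check_finite_vector <- function(x, name) {
  if (length(x) == 0L) {
    stop("invalid input: '", name, "' is empty")
  }
  x <- as.numeric(x)
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop("invalid input: non-finite component in '", name,
         "' at index ", bad[1L])
  }
  x
}
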