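#' Concentric radial-shell dataset
#'
#' Seeded generator realising the classifier's separability premise: one
#' class inside a sphere, the other outside it. Inside-class patterns are
#' drawn uniformly in the ball of radius `inner_radius` over the informative
#' dimensions; outside-class patterns sit on the shell with radial norm
#' uniform in `[outer_radius, 2 * outer_radius]`. Directions are sampled on
#' the positive orthant, mimicking nonnegative expression-like intensities;
#' this also makes the below/above T-means orientation agree with the
#' inside/outside radial geometry. `noise_dims` standard-normal columns
#' carrying no class signal are appended after the informative columns, so
#' attribute-selection correctness is directly checkable.
#'
#' @param n1,n2 patterns in classes 1 and 2.
#' @param informative_dims number of informative (shell) dimensions.
#' @param noise_dims number of pure-noise dimensions appended.
#' @param inner_radius,outer_radius ball and shell radii,
#'   `0 <= inner < outer`.
#' @param inside_class which class (1 or 2) occupies the inner ball.
#' @param seed integer seed; the output is a deterministic function of the
#'   spec.
#' @return An [mml_data] with `n1 + n2` rows; class 1 rows come first.
#'   Informative columns are named `inf1..`, noise columns `noise1..`.
#' @examples
#' d <- radial_shells(seed = 7)
#' range(sqrt(rowSums(d$x[d$y == 1, 1:3]^2))) # inside the unit ball
#' @export
radial_shells <- function(n1 = 15L, n2 = 15L, informative_dims = 3L,
                          noise_dims = 50L, inner_radius = 1,
                          outer_radius = 5, inside_class = 1L, seed = 1L) {
  if (inner_radius < 0 || outer_radius <= inner_radius) {
    stop("configuration error: need 0 <= inner_radius < outer_radius")
  }
  if (!inside_class %in% c(1L, 2L)) stop("'inside_class' must be 1 or 2")
  set.seed(seed)
  d <- informative_dims
  # uniform directions on the positive orthant of the unit sphere
  directions <- function(n) {
    g <- abs(matrix(stats::rnorm(n * d), n, d))
    g / sqrt(rowSums(g^2))
  }
  n_in <- if (inside_class == 1L) n1 else n2
  n_out <- if (inside_class == 1L) n2 else n1
  # radius^(1/d) scaling gives uniformity in the ball
  x_in <- directions(n_in) * (inner_radius * stats::runif(n_in)^(1 / d))
  x_out <- directions(n_out) * stats::runif(n_out, outer_radius,
                                            2 * outer_radius)
  x <- if (inside_class == 1L) rbind(x_in, x_out) else rbind(x_out, x_in)
  if (noise_dims > 0L) {
    x <- cbind(x, matrix(stats::rnorm((n1 + n2) * noise_dims),
                         n1 + n2, noise_dims))
  }
  colnames(x) <- c(paste0("inf", seq_len(d)),
                   if (noise_dims > 0L) paste0("noise", seq_len(noise_dims)))
  mml_data(x, rep(c("1", "2"), c(n1, n2)), positive = "1")
}

#' Imbalanced Gaussian-cloud dataset
#'
#' Two spherical Gaussian clouds whose informative-dimension means differ by
#' `mean_shift`; emulates the microarray regime (attributes can far exceed
#' patterns, imbalance ratios up to ~4.3). With `mean_shift = 0` the classes
#' are indistinguishable and any classifier's balanced accuracy concentrates
#' around 0.5.
#'
#' @param n1,n2 class sizes (>= 2 each).
#' @param dims informative dimensions.
#' @param mean_shift separation of the class means along every informative
#'   dimension.
#' @param noise_dims standard-normal noise columns appended.
#' @param seed integer seed.
#' @return An [mml_data]; the attribute `imbalance_ratio` records
#'   `max(n1, n2) / min(n1, n2)`.
#' @examples
#' d <- gaussian_imbalanced(61, 260, dims = 5, mean_shift = 3, seed = 1)
#' attr(d, "imbalance_ratio") # 4.26
#' @export
gaussian_imbalanced <- function(n1, n2, dims = 5L, mean_shift = 2,
                                noise_dims = 0L, seed = 1L) {
  if (n1 < 2L || n2 < 2L) stop("need at least 2 patterns per class")
  set.seed(seed)
  x1 <- matrix(stats::rnorm(n1 * dims), n1, dims)
  x2 <- matrix(stats::rnorm(n2 * dims, mean = mean_shift), n2, dims)
  x <- rbind(x1, x2)
  if (noise_dims > 0L) {
    x <- cbind(x, matrix(stats::rnorm((n1 + n2) * noise_dims),
                         n1 + n2, noise_dims))
  }
  colnames(x) <- c(paste0("inf", seq_len(dims)),
                   if (noise_dims > 0L) paste0("noise", seq_len(noise_dims)))
  out <- mml_data(x, rep(c("1", "2"), c(n1, n2)), positive = "1")
  attr(out, "imbalance_ratio") <- max(n1, n2) / min(n1, n2)
  out
}

#' Inject missing cells into a dataset
#'
#' Marks the stated fraction of cells `NA`, uniformly at random over the
#' cell grid, but never blanks an entire column (so fold-wise column-mean
#' imputation always has support).
#'
#' @param data an [mml_data] object.
#' @param fraction fraction of cells to blank, in `[0, 1)`.
#' @param seed integer seed.
#' @return The dataset with `round(fraction * length(x))` cells set to `NA`.
#' @export
inject_missing <- function(data, fraction, seed = 1L) {
  if (!inherits(data, "mml_data")) stop("'data' must be an mml_data object")
  if (fraction < 0 || fraction >= 1) {
    stop("configuration error: 'fraction' must lie in [0, 1)")
  }
  if (fraction == 0) return(data)
  set.seed(seed)
  x <- data$x
  n_cells <- length(x)
  n_miss <- round(fraction * n_cells)
  n_row <- nrow(x)
  repeat {
    idx <- sample.int(n_cells, n_miss)
    cols <- ((idx - 1L) %/% n_row) + 1L
    if (!any(tabulate(cols, ncol(x)) == n_row)) break
  }
  x[idx] <- NA_real_
  data$x <- x
  data
}
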