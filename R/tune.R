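#' Differential-evolution control settings
#'
#' Canonical DE/rand/1 settings for the two-dimensional integer search over
#' (att, bound). `att_range` defaults at fit time to
#' `c(bound_range[1], min(L, 200))` where L is the attribute count.
#'
#' @param np population size (>= 4, so three distinct donors plus the target
#'   exist).
#' @param F mutation factor in (0, 2].
#' @param pR recombination probability in \[0, 1\].
#' @param G number of generations.
#' @param att_range integer interval for `att`, or `NULL` to derive from the
#'   data.
#' @param bound_range integer interval for `bound`.
#' @param crossover `"binomial"` for per-coordinate binomial crossover with a
#'   guaranteed mutant coordinate, or `"gate"` for a single acceptance gate
#'   on the whole mutant (the proposal is only evaluated with probability
#'   `pR`).
#' @return A list of class `"de_control"`.
#' @export
de_control <- function(np = 20L, F = 0.5, pR = 0.9, G = 30L,
                       att_range = NULL, bound_range = c(1L, 15L),
                       crossover = c("binomial", "gate")) {
  crossover <- match.arg(crossover)
  if (np < 4L) stop("configuration error: 'np' must be at least 4")
  if (F <= 0 || F > 2) stop("configuration error: 'F' must lie in (0, 2]")
  if (pR < 0 || pR > 1) stop("configuration error: 'pR' must lie in [0, 1]")
  if (G < 0L) stop("configuration error: 'G' must be non-negative")
  structure(list(np = as.integer(np), F = F, pR = pR, G = as.integer(G),
                 att_range = att_range, bound_range = as.integer(bound_range),
                 crossover = crossover),
            class = "de_control")
}

# round half away from zero, deterministically across platforms
round_half_away <- function(z) {
  sign(z) * floor(abs(z) + 0.5)
}

# clamp into the integer box and repair bound <= att
repair_individual <- function(v, att_range, bound_range) {
  att <- as.integer(max(att_range[1L], min(att_range[2L], v[1L])))
  bound <- as.integer(max(bound_range[1L], min(bound_range[2L], v[2L])))
  if (bound > att) bound <- att
  c(att = att, bound = bound)
}

# uniform seeded initial population, np x 2 integer matrix
de_init_population <- function(control) {
  att <- sample(seq(control$att_range[1L], control$att_range[2L]),
                control$np, replace = TRUE)
  bound <- sample(seq(control$bound_range[1L], control$bound_range[2L]),
                  control$np, replace = TRUE)
  pop <- cbind(att = att, bound = bound)
  t(apply(pop, 1L, repair_individual,
          att_range = control$att_range, bound_range = control$bound_range))
}

#' Propose a differential-evolution trial individual
#'
#' Builds the mutant `x_c + F * (x_a - x_b)` from three donors distinct from
#' the target, rounds half away from zero, applies crossover against the
#' target (binomial with one guaranteed mutant coordinate, or the
#' single-gate variant where the mutant is taken whole), and repairs the
#' result into the bounds with `bound <= att`.
#'
#' @param target_index row index of the target individual.
#' @param population integer matrix with columns `att`, `bound`.
#' @param control a [de_control()] object with `att_range` resolved.
#' @return Named integer vector `c(att, bound)`. In `"gate"` mode the
#'   attribute `"evaluate"` is `FALSE` when the gate rejected the mutant (the
#'   target survives unchallenged).
#' @export
de_propose <- function(target_index, population, control) {
  np <- nrow(population)
  if (np < 4L) stop("configuration error: population size must be at least 4")
  donors <- sample(setdiff(seq_len(np), target_index), 3L)
  xa <- population[donors[1L], ]
  xb <- population[donors[2L], ]
  xc <- population[donors[3L], ]
  mutant <- round_half_away(xc + control$F * (xa - xb))
  evaluate <- TRUE
  if (control$crossover == "binomial") {
    trial <- population[target_index, ]
    j_rand <- sample(2L, 1L)
    for (j in 1:2) {
      if (j == j_rand || stats::runif(1L) < control$pR) {
        trial[j] <- mutant[j]
      }
    }
  } else {
    trial <- mutant
    evaluate <- stats::runif(1L) < control$pR
  }
  out <- repair_individual(trial, control$att_range, control$bound_range)
  attr(out, "evaluate") <- evaluate
  out
}

#' Self-adjust (att, bound) by differential evolution
#'
#' Minimises the training error of [mml()] over the integer box of
#' hyperparameters. Replacement is greedy: a trial replaces its target only
#' when its training error is strictly smaller, so the best fitness per
#' generation is non-increasing. With a fixed seed the whole search is
#' reproducible bit for bit. Fitness evaluations are memoised on (att,
#' bound) since the learning phase is deterministic.
#'
#' @param x an [mml_data] object or numeric matrix.
#' @param y labels when `x` is a matrix.
#' @param control a [de_control()] configuration.
#' @param seed integer seed for the search, or `NULL` to use the current RNG
#'   state.
#' @param positive label coded as class 1 when `x` is a matrix.
#' @return An object of class `"mml_tune"`: list with `best` (list `att`,
#'   `bound`, `fitness`), `model` (the fitted [mml] at the best setting),
#'   `history` (best fitness after initialisation and each generation,
#'   non-increasing), `evaluations`, and `control`.
#' @examples
#' d <- radial_shells(seed = 7)
#' tn <- mml_tune(d, control = de_control(np = 8, G = 5), seed = 1)
#' tn$best
#' @export
mml_tune <- function(x, y = NULL, control = de_control(), seed = NULL,
                     positive = NULL) {
  d <- if (inherits(x, "mml_data")) x else mml_data(x, y, positive = positive)
  if (anyNA(d$x)) stop("missing values in 'x'; impute first")
  L <- ncol(d$x)
  if (is.null(control$att_range)) {
    control$att_range <- c(control$bound_range[1L], min(L, 200L))
  }
  control$att_range <- as.integer(control$att_range)
  if (control$att_range[1L] > control$att_range[2L] ||
      control$bound_range[1L] > control$bound_range[2L]) {
    stop("configuration error: empty hyperparameter interval")
  }
  if (!is.null(seed)) set.seed(seed)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness <- function(ind) {
    key <- paste(ind[1L], ind[2L])
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    err <- suppressWarnings(
      learn_phase(d$x, d$y, ind[1L], ind[2L])$training_error
    )
    cache[[key]] <- err
    err
  }

  pop <- de_init_population(control)
  fit <- apply(pop, 1L, fitness)
  history <- min(fit)
  for (gen in seq_len(control$G)) {
    for (i in seq_len(control$np)) {
      trial <- de_propose(i, pop, control)
      if (!isTRUE(attr(trial, "evaluate"))) next
      f_trial <- fitness(trial)
      if (f_trial < fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
    history <- c(history, min(fit))
  }
  best_i <- which.min(fit)
  best <- list(att = unname(pop[best_i, 1L]),
               bound = unname(pop[best_i, 2L]),
               fitness = unname(fit[best_i]))
  model <- suppressWarnings(
    new_mml(learn_phase(d$x, d$y, best$att, best$bound), d, NULL)
  )
  structure(
    list(best = best, model = model, history = history,
         evaluations = n_eval, control = control),
    class = "mml_tune"
  )
}

#' @export
print.mml_tune <- function(x, ...) {
  cat("Differential-evolution hyperparameter search\n")
  cat(sprintf("  best: att = %d, bound = %d, training error = %d\n",
              x$best$att, x$best$bound, x$best$fitness))
  cat(sprintf("  %d generations, %d fitness evaluations\n",
              length(x$history) - 1L, x$evaluations))
  cat("  best-fitness history:",
      paste(utils::head(x$history, 12), collapse = " "),
      if (length(x$history) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.mml_tune <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "generation", ylab = "best training error", ...)
  invisible(x)
}
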