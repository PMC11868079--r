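# Brute-force re-implementation of the learning phase with direct loops and
# repeated-minimum selection instead of vectorised code and sort(): the
# independent oracle the fast path is checked against on small problems.

oracle_rank <- function(errors, att) {
  remaining <- seq_along(errors)
  picked <- integer(0)
  while (length(picked) < att && length(remaining) > 0) {
    best <- remaining[1]
    for (j in remaining) {
      if (errors[j] < errors[best]) best <- j
    }
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  picked
}

oracle_learn <- function(x, y, att, bound) {
  Y1 <- x[y == 1, , drop = FALSE]
  Y2 <- x[y == 2, , drop = FALSE]
  L <- ncol(x)
  e1 <- e2 <- integer(L)
  tm <- numeric(L)
  for (j in seq_len(L)) {
    m1 <- sum(Y1[, j]) / nrow(Y1)
    m2 <- sum(Y2[, j]) / nrow(Y2)
    tm[j] <- (m1 + m2) / 2
    for (v in Y1[, j]) {
      if (v > tm[j]) e1[j] <- e1[j] + 1
      if (v < tm[j]) e2[j] <- e2[j] + 1
    }
    for (v in Y2[, j]) {
      if (v < tm[j]) e1[j] <- e1[j] + 1
      if (v > tm[j]) e2[j] <- e2[j] + 1
    }
  }
  c1_in <- mean(e1) < mean(e2)
  att <- min(att, L)
  cand <- oracle_rank(if (c1_in) e1 else e2, att)

  att_errors <- integer(att)
  for (i in seq_len(att)) {
    r1 <- numeric(0)
    r2 <- numeric(0)
    for (k in seq_len(nrow(Y1))) r1 <- c(r1, sqrt(Y1[k, cand[i]]^2))
    for (k in seq_len(nrow(Y2))) r2 <- c(r2, sqrt(Y2[k, cand[i]]^2))
    b <- if (c1_in) (max(r1) + min(r2)) / 2 else (min(r1) + max(r2)) / 2
    n_err <- 0
    for (r in r1) if ((c1_in && r > b) || (!c1_in && r < b)) n_err <- n_err + 1
    for (r in r2) if ((c1_in && r < b) || (!c1_in && r > b)) n_err <- n_err + 1
    att_errors[i] <- n_err
  }
  sel <- cand[oracle_rank(att_errors, min(bound, att))]

  bound <- length(sel)
  boundaries <- numeric(bound)
  per_set <- integer(bound)
  for (k in seq_len(bound)) {
    r1 <- apply(Y1[, sel[1:k], drop = FALSE], 1,
                function(v) sqrt(sum(v^2)))
    r2 <- apply(Y2[, sel[1:k], drop = FALSE], 1,
                function(v) sqrt(sum(v^2)))
    boundaries[k] <- if (c1_in) (max(r1) + min(r2)) / 2 else
      (min(r1) + max(r2)) / 2
    n_err <- 0
    for (r in r1) {
      if ((c1_in && r > boundaries[k]) || (!c1_in && r < boundaries[k])) {
        n_err <- n_err + 1
      }
    }
    for (r in r2) {
      if ((c1_in && r < boundaries[k]) || (!c1_in && r > boundaries[k])) {
        n_err <- n_err + 1
      }
    }
    per_set[k] <- n_err
  }
  list(e1 = as.integer(e1), e2 = as.integer(e2), c1_in = c1_in,
       candidates = as.integer(cand),
       learning_attributes = as.integer(sel), boundaries = boundaries,
       per_set_errors = as.integer(per_set),
       training_error = as.integer(min(per_set)))
}

# random small dataset; integer-ish values provoke threshold and radius ties
random_small_data <- function() {
  N <- sample(4:12, 1)
  L <- sample(2:6, 1)
  y <- integer(N)
  y[sample(N, 2)] <- 1:2 # guarantee both classes
  y[y == 0] <- sample(1:2, sum(y == 0), replace = TRUE)
  x <- matrix(sample(-5:5, N * L, replace = TRUE) +
                sample(c(0, 0.5), N * L, replace = TRUE), N, L)
  list(x = x, y = y)
}
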