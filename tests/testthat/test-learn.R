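test_that("split_by_class partitions rows and rejects one-class input", {
  x <- matrix(1:12, 3, 4)
  sp <- split_by_class(x, c(1, 2, 1))
  expect_equal(sp$Y1, x[c(1, 3), ])
  expect_equal(sp$Y2, x[2, , drop = FALSE])
  expect_error(split_by_class(x, c(1, 1, 1)), "degenerate")

  d <- radial_shells(n1 = 20, n2 = 16, noise_dims = 2, seed = 2)
  sp <- split_by_class(d)
  expect_equal(nrow(sp$Y1) + nrow(sp$Y2), 36)
})

test_that("t_means is the midpoint of the class means", {
  tm <- t_means(matrix(c(0, 2)), matrix(c(3, 5)))
  expect_equal(tm$m1, 1)
  expect_equal(tm$m2, 4)
  expect_equal(tm$t_means, 2.5)

  y <- matrix(c(1, 5, 9))
  expect_equal(t_means(y, y)$t_means, mean(y))

  set.seed(21)
  Y1 <- matrix(rnorm(15), 5, 3)
  Y2 <- matrix(rnorm(15), 5, 3)
  expect_equal(t_means(Y1, Y2)$t_means,
               (colMeans(Y1) + colMeans(Y2)) / 2, tolerance = 1e-12)
  expect_error(t_means(Y1, Y2[, 1:2]), "shape")
})

test_that("error vectors count strict threshold violations per orientation", {
  # 3 class-1 values above and 4 class-2 values below the threshold
  Y1 <- matrix(c(-1, -2, 1, 2, 3))      # 3 above 0
  Y2 <- matrix(c(-1, -2, -3, -4, 5, 6)) # 4 below 0
  ev <- error_vectors(Y1, Y2, 0)
  expect_equal(ev$e1, 7L)
  # mirror orientation: class 1 below (2) + class 2 above (2)
  expect_equal(ev$e2, 4L)

  # 14 class-1 below + 14 class-2 above
  ev <- error_vectors(matrix(rep(-1, 14)), matrix(rep(1, 14)), 0)
  expect_equal(ev$e2, 28L)
  expect_equal(ev$e1, 0L)

  # values equal to the threshold count in neither orientation
  ev <- error_vectors(matrix(c(0, 0, 1)), matrix(c(0, -1)), 0)
  expect_equal(ev$e1, 2L) # one class-1 above + one class-2 below
  expect_equal(ev$e2, 0L)
  expect_equal(5L - ev$e1 - ev$e2, 3L) # the three zeros sit on the threshold
})

test_that("e1 + e2 + threshold ties account for every pattern", {
  set.seed(22)
  for (i in 1:20) {
    d <- random_small_data()
    sp <- split_by_class(d$x, d$y)
    tm <- t_means(sp$Y1, sp$Y2)
    ev <- error_vectors(sp$Y1, sp$Y2, tm$t_means)
    ties <- colSums(sweep(sp$Y1, 2, tm$t_means, "==")) +
      colSums(sweep(sp$Y2, 2, tm$t_means, "=="))
    expect_equal(ev$e1 + ev$e2 + as.integer(ties),
                 rep(nrow(d$x), ncol(d$x)))
  }
})

test_that("orientation is strict and ties resolve to class 1 outside", {
  expect_false(orientation(c(17, 18), c(17, 18))) # equal means
  expect_true(orientation(c(0, 0), c(1, 1)))
  # means 17.5355 vs 17.4606: class 1 is NOT below
  expect_false(orientation(c(17.5355, 17.5355), c(17.4606, 17.4606)))
})

test_that("swapping class labels swaps e1/e2 and flips the orientation", {
  set.seed(23)
  for (i in 1:10) {
    d <- random_small_data()
    sp <- split_by_class(d$x, d$y)
    tm <- t_means(sp$Y1, sp$Y2)$t_means
    ev <- error_vectors(sp$Y1, sp$Y2, tm)
    ev_sw <- error_vectors(sp$Y2, sp$Y1,
                           t_means(sp$Y2, sp$Y1)$t_means)
    expect_equal(ev_sw$e1, ev$e2)
    expect_equal(ev_sw$e2, ev$e1)
    if (mean(ev$e1) != mean(ev$e2)) {
      expect_equal(orientation(ev_sw$e1, ev_sw$e2),
                   !orientation(ev$e1, ev$e2))
    }
  }
})

test_that("attribute ranking is stable, ascending, and clamps att", {
  rk <- rank_attributes(c(5, 1, 3), 2)
  expect_equal(rk$ordered_indices, c(2, 3))
  expect_equal(rk$ordered_errors, c(1, 3))

  rk <- rank_attributes(c(2, 2, 2), 3)
  expect_equal(rk$ordered_indices, 1:3)

  expect_equal(rank_attributes(0L, 1)$ordered_indices, 1)
  expect_warning(rk <- rank_attributes(c(4, 2), 5), "clamped")
  expect_equal(rk$ordered_indices, c(2, 1))

  set.seed(24)
  for (i in 1:10) {
    e <- sample(0:3, 8, replace = TRUE)
    expect_equal(rank_attributes(e, 8)$ordered_indices, oracle_rank(e, 8))
  }
})

test_that("the spherical frontier is the midpoint of adjacent extremes", {
  expect_equal(attribute_radius(c(1, 2, 3), c(5, 6, 7), TRUE), 4)
  expect_equal(attribute_radius(c(5, 6, 7), c(1, 2, 3), FALSE), 4)
  set.seed(25)
  for (i in 1:10) {
    r1 <- runif(6, 0, 10)
    r2 <- runif(7, 0, 10)
    b <- attribute_radius(r1, r2, TRUE)
    expect_equal(b, (max(r1) + min(r2)) / 2)
    expect_true(b >= min(max(r1), min(r2)) && b <= max(max(r1), min(r2)))
  }
  expect_error(attribute_radius(numeric(0), 1, TRUE), "degenerate")
})

test_that("boundary errors use strict inequalities in both orientations", {
  # 16 class-1 radii inside + 1 class-2 radius outside, class 1 outside
  set.seed(29)
  r1 <- c(runif(16, 0, 4), 9)
  r2 <- c(runif(14, 0, 4), 10)
  expect_equal(boundary_errors(r1, r2, 5, c1_in = FALSE), 16 + 1)
  expect_equal(boundary_errors(1, 9, 5, c1_in = TRUE), 0)
  # radii exactly on the boundary are not errors
  expect_equal(boundary_errors(c(5, 5), c(5, 5), 5, TRUE), 0)
  expect_equal(boundary_errors(c(5, 5), c(5, 5), 5, FALSE), 0)
})

test_that("progressive boundaries cover nested prefixes with growing norms", {
  pb <- progressive_boundaries(matrix(3), matrix(7), 1, TRUE)
  expect_equal(pb$boundaries, 5)
  expect_equal(pb$per_set_errors, 0L)

  # class 1 at the origin, class 2 on a shell of radius 10
  set.seed(26)
  Y1 <- matrix(0, 5, 2)
  ang <- runif(5)
  Y2 <- 10 * cbind(cos(ang), sin(ang))
  pb <- progressive_boundaries(Y1, Y2, 2, TRUE)
  expect_true(all(diff(pb$boundaries) > 0))
  expect_equal(pb$per_set_errors, c(0L, 0L))
  expect_warning(progressive_boundaries(Y1, Y2, 3, TRUE), "clamped")
})

test_that("a perfectly separating attribute yields training error zero", {
  set.seed(27)
  x <- cbind(sep = c(runif(6, 0, 1), runif(7, 5, 9)),
             junk = rnorm(13))
  y <- rep(c(1, 2), c(6, 7))
  fit <- mml(x, y, att = 2, bound = 1)
  expect_equal(fit$training_error, 0L)
  expect_equal(fit$learning_attributes, 1L)
})

test_that("the learning phase matches the brute-force oracle exactly", {
  set.seed(28)
  for (i in 1:40) {
    d <- random_small_data()
    att <- sample(ncol(d$x), 1)
    bound <- sample(att, 1)
    lp <- sphereMML:::learn_phase(d$x, d$y, att, bound)
    or <- oracle_learn(d$x, d$y, att, bound)
    expect_identical(lp$e1, or$e1)
    expect_identical(lp$e2, or$e2)
    expect_identical(lp$c1_in, or$c1_in)
    expect_identical(lp$candidates, or$candidates)
    expect_identical(lp$learning_attributes, or$learning_attributes)
    expect_equal(lp$boundaries, or$boundaries)
    expect_identical(lp$per_set_errors, or$per_set_errors)
    expect_identical(lp$training_error, or$training_error)
  }
})

test_that("att can be given as a percentage of the attribute count", {
  d <- radial_shells(n1 = 6, n2 = 6, noise_dims = 7, seed = 3) # L = 10
  fit <- mml(d, att = 50, bound = 2, att_percent = TRUE)
  expect_equal(fit$att, 5L)
  expect_length(fit$candidates, 5L)
})

test_that("the fit object carries a coherent model summary surface", {
  d <- radial_shells(seed = 7)
  fit <- mml(d, att = ncol(d$x), bound = 3)
  expect_s3_class(fit, "mml")
  expect_length(coef(fit), fit$bound)
  expect_equal(length(fit$learning_attributes), length(fit$boundaries))
  expect_output(print(fit), "training error")
  expect_output(print(summary(fit)), "Progressive sets")
})

test_that("the formula interface fits and predicts from data frames", {
  d <- as.data.frame(radial_shells(n1 = 8, n2 = 8, noise_dims = 4, seed = 4))
  fit <- mml(class ~ ., data = d, att = 7, bound = 3)
  pred <- predict(fit, d[, setdiff(names(d), "class")])
  expect_equal(as.character(pred), d$class)
})
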