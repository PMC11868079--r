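test_that("control settings are validated", {
  expect_error(de_control(np = 3), "np")
  expect_error(de_control(F = 0), "F")
  expect_error(de_control(pR = 1.2), "pR")
  expect_s3_class(de_control(), "de_control")
})

test_that("a point search interval collapses the population", {
  d <- radial_shells(n1 = 6, n2 = 6, noise_dims = 5, seed = 8)
  tn <- mml_tune(d, control = de_control(np = 6, G = 1,
                                         att_range = c(5, 5),
                                         bound_range = c(2, 2)),
                 seed = 1)
  expect_equal(tn$best$att, 5L)
  expect_equal(tn$best$bound, 2L)
})

test_that("the mutant combines donors as xc + F (xa - xb)", {
  ctl <- de_control(np = 4, F = 1, pR = 1, att_range = c(1, 100),
                    bound_range = c(1, 100))
  pop <- rbind(c(50, 50), c(12, 5), c(8, 1), c(10, 3))
  colnames(pop) <- c("att", "bound")
  # pR = 1 forces every coordinate from the mutant; donors are rows 2:4 in
  # some order, so the proposal is a permutation of xc + (xa - xb)
  possible <- list(c(14, 7), c(6, -1), c(4, 3), c(12, 5), c(8, 1), c(10, 3))
  possible <- lapply(possible, function(v)
    sphereMML:::repair_individual(v, c(1, 100), c(1, 100)))
  set.seed(41)
  for (i in 1:10) {
    prop <- de_propose(1, pop, ctl)
    expect_true(any(vapply(possible, function(v)
      all(v == prop), logical(1))))
  }
})

test_that("xa == xb degenerates the mutant to xc", {
  ctl <- de_control(np = 4, F = 0.5, pR = 1, att_range = c(1, 100),
                    bound_range = c(1, 100))
  pop <- rbind(c(50, 50), c(7, 4), c(7, 4), c(7, 4))
  set.seed(42)
  prop <- de_propose(1, pop, ctl)
  expect_equal(as.integer(prop), c(7L, 4L))
})

test_that("proposals always satisfy the bounds and bound <= att", {
  set.seed(43)
  ctl <- de_control(np = 8, F = 1.8, pR = 0.5, att_range = c(2, 30),
                    bound_range = c(1, 20))
  pop <- cbind(att = sample(2:30, 8, TRUE), bound = sample(1:20, 8, TRUE))
  pop <- t(apply(pop, 1, sphereMML:::repair_individual, c(2, 30), c(1, 20)))
  for (i in 1:200) {
    prop <- de_propose(sample(8, 1), pop, ctl)
    expect_true(prop["att"] >= 2 && prop["att"] <= 30)
    expect_true(prop["bound"] >= 1 && prop["bound"] <= 20)
    expect_true(prop["bound"] <= prop["att"])
  }
})

test_that("rounding is half away from zero", {
  expect_equal(sphereMML:::round_half_away(c(1.5, 2.5, -1.5, -0.4, 0.5)),
               c(2, 3, -2, 0, 1))
})

test_that("evolution is seed-reproducible with a non-increasing history", {
  d <- radial_shells(n1 = 8, n2 = 8, noise_dims = 10, seed = 9)
  ctl <- de_control(np = 8, G = 6)
  t1 <- mml_tune(d, control = ctl, seed = 5)
  t2 <- mml_tune(d, control = ctl, seed = 5)
  expect_identical(t1$best, t2$best)
  expect_identical(t1$history, t2$history)
  expect_true(all(diff(t1$history) <= 0))
  expect_length(t1$history, 7) # init + G generations
})

test_that("G = 0 returns the best of the initial population", {
  d <- radial_shells(n1 = 6, n2 = 6, noise_dims = 5, seed = 10)
  tn <- mml_tune(d, control = de_control(np = 10, G = 0), seed = 2)
  expect_length(tn$history, 1)
  expect_equal(tn$best$fitness, tn$history[1])
})

test_that("the returned model's training error equals the best fitness", {
  d <- radial_shells(n1 = 8, n2 = 8, noise_dims = 10, seed = 11)
  tn <- mml_tune(d, control = de_control(np = 8, G = 4), seed = 3)
  refit <- mml(d, att = tn$best$att, bound = tn$best$bound)
  expect_equal(tn$model$training_error, tn$best$fitness)
  expect_equal(refit$training_error, tn$best$fitness)
})

test_that("the gate crossover variant also repairs and reproduces", {
  d <- radial_shells(n1 = 6, n2 = 6, noise_dims = 5, seed = 12)
  ctl <- de_control(np = 6, G = 3, crossover = "gate")
  t1 <- mml_tune(d, control = ctl, seed = 4)
  t2 <- mml_tune(d, control = ctl, seed = 4)
  expect_identical(t1$history, t2$history)
  expect_true(all(diff(t1$history) <= 0))
})

test_that("self-adjustment is reachable straight from mml()", {
  d <- radial_shells(n1 = 8, n2 = 8, noise_dims = 10, seed = 13)
  fit <- mml(d, control = de_control(np = 6, G = 3), seed = 6)
  expect_s3_class(fit, "mml")
  expect_false(is.null(fit$tuning))
  expect_equal(fit$training_error, fit$tuning$best$fitness)
})
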