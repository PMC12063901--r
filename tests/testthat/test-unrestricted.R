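test_that("envelope_solve reproduces hand-worked cases", {
  # all +1 labels: single step right after the pinned first value
  expect_equal(envelope_solve(rep(1, 5), rep(1, 5), lambda = 0.5),
               c(0, 1, 1, 1, 1))
  # negative target clipped by monotonicity + pinning
  expect_equal(envelope_solve(c(1, -1), c(1, 1), lambda = 0.5), c(0, 0))
  # pooled block: (2 + 1) / 2 = 1.5 over positions 2-3
  expect_equal(envelope_solve(c(-1, 1, 1), c(1, 2, 1), lambda = 0.5),
               c(0, 1.5, 1.5))
})

test_that("envelope_solve validates arguments", {
  expect_error(envelope_solve(c(1, -1), c(1, 1), lambda = 0), "positive")
  expect_error(envelope_solve(c(1, -1), c(1, 1), lambda = -1), "positive")
  expect_error(envelope_solve(c(1, -1), c(1), lambda = 1), "equal length")
  expect_error(envelope_solve(c(1, -1), c(1, 0), lambda = 1), "positive")
})

test_that("envelope_solve matches the exhaustive oracle on small instances", {
  set.seed(101)
  for (rep in 1:60) {
    P <- sample(2:9, 1)
    y <- sample(c(-1, 1), P, replace = TRUE)
    w <- sample(1:5, P, replace = TRUE)
    lambda <- runif(1, 0.1, 2)
    I <- envelope_solve(y, w, lambda)
    oracle <- envelope_oracle(y, w, lambda)
    expect_lte(staircase_objective(I, y, w, lambda) - oracle$objective, 1e-8)
    expect_true(kkt_certificate(I, y, w, lambda))
    expect_true(all(diff(I) >= 0) && I[1] == 0 && all(I >= 0))
  }
})

test_that("envelope_solve matches the isotonic-regression oracle at larger P", {
  set.seed(202)
  for (rep in 1:10) {
    P <- sample(50:200, 1)
    y <- sample(c(-1, 1), P, replace = TRUE)
    w <- sample(1:10, P, replace = TRUE)
    lambda <- runif(1, 0.2, 1.5)
    expect_equal(envelope_solve(y, w, lambda), isotonic_oracle(y, w, lambda),
                 tolerance = 1e-10)
  }
})

test_that("solutions scale exactly as 1/lambda", {
  set.seed(3)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  w <- sample(1:4, 40, replace = TRUE)
  base <- envelope_solve(y, w, 0.5)
  expect_equal(envelope_solve(y, w, 2), base * 0.5 / 2, tolerance = 1e-12)
  expect_equal(envelope_solve(y, w, 0.1), base * 0.5 / 0.1, tolerance = 1e-12)
})

test_that("tied inputs pool into one transmission value", {
  # groups: {1,2}, {3,4}, {5}; pooled contributions sum y*w within groups
  y <- c(1, -1, 1, 1, -1)
  w <- c(1, 1, 2, 1, 1)
  g <- c(1, 1, 2, 2, 3)
  I <- envelope_solve(y, w, 0.5, groups = g)
  expect_equal(I[1], I[2])
  expect_equal(I[3], I[4])
  # pooled problem is the grouped quadratic: check against exhaustive oracle
  # on the expanded instance restricted to group-constant sequences
  obj <- staircase_objective(I, y, w, 0.5)
  grid_best <- Inf
  for (v2 in seq(0, 4, by = 0.01)) for (v3 in seq(0, 4, by = 0.01)) {
    if (v3 < v2) next
    o <- staircase_objective(c(0, 0, v2, v2, v3), y, w, 0.5)
    grid_best <- min(grid_best, o)
  }
  expect_lte(obj, grid_best + 1e-6)
})

test_that("axon_transmission follows the right-continuous step convention", {
  ax <- parsyn:::staircase_axon(c(0.2, 0.5, 0.8), 1:3, c(0, 1, 1))
  expect_equal(axon_transmission(ax, 0.1), 0)     # below all breakpoints
  expect_equal(axon_transmission(ax, 0.5), 1)     # at a breakpoint
  expect_equal(axon_transmission(ax, 0.6), 1)     # between breakpoints
  expect_equal(axon_transmission(ax, 0.95), 1)    # above all breakpoints
  expect_equal(axon_transmission(ax, c(0.2, 0.45)), c(0, 0))
})

test_that("train_unrestricted solves a separable 1-axon task in one pass", {
  ps <- pattern_set(matrix(c(0.2, 0.8)), c(-1, 1))
  fit <- train_unrestricted(ps, lambda = 0.5)
  expect_true(fit$success)
  expect_identical(fit$iterations_used, 1L)
  expect_identical(predict(fit$model, ps), ps$labels)
})

test_that("importance weights increment by one exactly for misclassified patterns", {
  set.seed(11)
  ps <- generate_patterns(2, 30, seed = 11)
  fit1 <- train_unrestricted(ps, lambda = 0.5, max_iter = 1)
  if (!fit1$success) {
    pred <- predict(fit1$model, ps)
    wrong <- pred != ps$labels
    expect_identical(fit1$weights, ifelse(wrong, 2, 1))
  }
  # weights never decrease with more iterations
  fit5 <- train_unrestricted(ps, lambda = 0.5, max_iter = 5)
  expect_true(all(fit5$weights >= fit1$weights))
})

test_that("axon order permutation leaves predictions unchanged", {
  set.seed(12)
  ps <- generate_patterns(4, 25, seed = 12)
  perm <- c(3, 1, 4, 2)
  ps_perm <- pattern_set(ps$inputs[, perm], ps$labels, ps$distribution)
  f1 <- train_unrestricted(ps, 0.5, max_iter = 50)
  f2 <- train_unrestricted(ps_perm, 0.5, max_iter = 50)
  expect_identical(f1$success, f2$success)
  expect_identical(predict(f1$model, ps), predict(f2$model, ps_perm))
})

test_that("trained staircases evaluate to their fitted values on training inputs", {
  set.seed(13)
  ps <- generate_patterns(3, 20, seed = 13)
  fit <- train_unrestricted(ps, 0.5, max_iter = 30)
  for (i in 1:3) {
    ax <- fit$model$axons[[i]]
    expect_equal(axon_transmission(ax, ax$sorted_inputs), ax$values)
    expect_true(all(diff(ax$values) >= 0))
    expect_equal(ax$values[1], 0)
  }
})

test_that("effective_synapse_count counts steps above the relative cut", {
  expect_equal(effective_synapse_count(c(5, 0.001, 0.004)), 1)
  expect_equal(effective_synapse_count(c(0, 0, 0)), 0L)
  expect_equal(effective_synapse_count(c(1, 1, 1)), 3)
  ax_flat <- parsyn:::staircase_axon(c(0.1, 0.9), 1:2, c(0, 0))
  expect_equal(effective_synapse_count(ax_flat), 0L)
})
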