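test_that("synapse_response evaluates the sigmoidal transmission function", {
  expect_equal(synapse_response(1, 5, 0.5, 0.5), 0.5)      # at threshold
  expect_equal(synapse_response(2, 0, 0.3, 0.9), 2.0)      # zero slope: a^2/2
  expect_equal(synapse_response(1, 10, 0.5, 1.0), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  expect_error(synapse_response(1, -1, 0, 0.5), "nonnegative")
})

test_that("synapse responses are bounded and monotone", {
  set.seed(21)
  for (rep in 1:20) {
    a <- runif(1, 0, 2); s <- runif(1, 0, 20); t <- runif(1)
    x <- sort(runif(50, -1, 2))
    h <- synapse_response(a, s, t, x)
    expect_true(all(h >= 0 & h <= a^2))
    expect_true(all(diff(h) >= 0))
  }
})

test_that("somatic_input sums synapse responses over all axons and synapses", {
  ps <- generate_patterns(3, 7, seed = 22)
  zero <- restricted_neuron(matrix(0, 3, 2), matrix(1, 3, 2),
                            matrix(0.5, 3, 2), 0)
  expect_equal(somatic_input(zero, ps), rep(0, 7))

  flat <- restricted_neuron(matrix(1, 2, 1), matrix(0, 2, 1),
                            matrix(0.3, 2, 1), 0)
  ps2 <- generate_patterns(2, 5, seed = 1)
  expect_equal(somatic_input(flat, ps2), rep(1, 5))  # two constant 0.5 responses

  for (form in c("sigmoid", "tanh")) {
    nr <- random_restricted(3, 2, form, seed = 23)
    expect_equal(somatic_input(nr, ps), somatic_bruteforce(nr, ps),
                 tolerance = 1e-10)
  }
  expect_error(somatic_input(zero, generate_patterns(4, 3, seed = 1)), "axons")
})

test_that("predict applies the declared sign convention", {
  ps <- generate_patterns(2, 4, seed = 24)
  zero <- restricted_neuron(matrix(0, 2, 1), matrix(1, 2, 1),
                            matrix(0.5, 2, 1), 0)
  expect_equal(predict(zero, ps), rep(-1, 4))          # z == theta ties to -1
  zero$soma_threshold <- -1
  expect_equal(predict(zero, ps), rep(1, 4))           # z - theta = 1 > 0

  nr <- random_restricted(2, 3, seed = 25)
  z <- somatic_input(nr, ps)
  expect_equal(predict(nr, ps), ifelse(z - nr$soma_threshold > 0, 1, -1))
})

test_that("hinge_loss and violating_set implement the margin algebra", {
  expect_equal(hinge_loss(c(0.2, -0.2), c(1, -1), 0, 0.1), 0)
  expect_equal(hinge_loss(0.05, 1, 0, 0.1), 0.05)
  expect_equal(hinge_loss(-1, 1, 0, 0.1), 1.1)
  expect_error(hinge_loss(c(1, 2), 1, 0, 0.1), "length")

  expect_identical(violating_set(c(0.2, -0.2), c(1, -1), 0, 0.1), integer(0))
  expect_identical(violating_set(0.1, 1, 0, 0.1), integer(0))  # strict: excluded
  set.seed(26)
  z <- rnorm(40); y <- sample(c(-1, 1), 40, TRUE); th <- 0.2; eps <- 0.3
  manual <- which(vapply(seq_along(z),
                         function(m) eps - (z[m] - th) * y[m] > 0, logical(1)))
  expect_identical(violating_set(z, y, th, eps), manual)
})

test_that("gradient_step is a no-op without violators and moves theta by the label sum", {
  ps <- pattern_set(matrix(0.5, 1, 1), 1)
  cfg <- train_config(eta_theta = 0.01)
  # all-zero amplitudes, theta = -1: pattern is correct with margin 1 > eps
  happy <- restricted_neuron(matrix(0, 1, 1), matrix(1, 1, 1),
                             matrix(0.5, 1, 1), -1)
  expect_identical(gradient_step(happy, ps, cfg), happy)

  # y = +1 misclassified (theta = +1): theta decreases by exactly eta_theta
  sad <- restricted_neuron(matrix(0, 1, 1), matrix(1, 1, 1),
                           matrix(0.5, 1, 1), 1)
  out <- gradient_step(sad, ps, cfg)
  expect_equal(out$soma_threshold, 1 - 0.01)
})

test_that("gradient_step equals minus the hinge-loss gradient (both forms)", {
  set.seed(27)
  cfg <- train_config(margin = 0.1, eta_a = 1, eta_s = 1, eta_t = 1,
                      eta_theta = 1)
  for (form in c("sigmoid", "tanh")) {
    for (rep in 1:10) {
      ps <- generate_patterns(2, 6, seed = 270 + rep)
      nr <- random_restricted(2, 2, form, seed = 280 + rep)
      up <- gradient_step(nr, ps, cfg)
      for (field in c("amp_root", "slope", "threshold")) {
        for (idx in seq_along(nr[[field]])) {
          g_fd <- fd_gradient(nr, ps, field, idx, cfg$margin)
          g_an <- -(up[[field]][idx] - nr[[field]][idx])
          expect_lt(abs(g_fd - g_an) / max(1e-8, abs(g_fd)), 1e-4)
        }
      }
      g_fd <- fd_gradient(nr, ps, "soma_threshold", 1, cfg$margin)
      expect_equal(-(up$soma_threshold - nr$soma_threshold), g_fd,
                   tolerance = 1e-6)
    }
  }
})

test_that("slope nonnegativity survives aggressive updates", {
  set.seed(28)
  ps <- generate_patterns(2, 10, seed = 28)
  nr <- random_restricted(2, 2, "tanh", seed = 28)
  cfg <- train_config(eta_a = 0.5, eta_s = 0.5, eta_t = 0.5, eta_theta = 0.5)
  for (k in 1:50) {
    nr <- gradient_step(nr, ps, cfg)
    expect_true(all(nr$slope >= 0))
  }
})

test_that("resurrection restores only sub-floor synapses, with in-range thresholds", {
  nr <- restricted_neuron(matrix(c(sqrt(0.02), 1e-3), 1, 2),
                          matrix(1, 1, 2), matrix(0.5, 1, 2), 0)
  out <- resurrect_synapses(nr, amp_floor = 0.01, input_range = c(0, 1),
                            seed = 9)
  expect_equal(out$amp_root[1, 1], sqrt(0.02))      # above floor: untouched
  expect_equal(out$threshold[1, 1], 0.5)
  expect_equal(out$amp_root[1, 2]^2, 0.01)          # restored to exactly floor
  expect_gte(out$threshold[1, 2], 0)
  expect_lte(out$threshold[1, 2], 1)
  expect_error(resurrect_synapses(nr, 0.01, c(1, 1)), "empty")
})

test_that("resurrected thresholds are edge-biased over the input range", {
  nr <- restricted_neuron(matrix(0, 100, 100), matrix(1, 100, 100),
                          matrix(0.5, 100, 100), 0)
  out <- resurrect_synapses(nr, 0.01, c(0, 1), seed = 30)
  t <- as.vector(out$threshold)
  edges <- sum(t <= 0.1 | t >= 0.9)
  middle <- sum(t >= 0.45 & t <= 0.55)
  # Beta(1/2,1/2): P(edges) ~ 0.41, P(middle) ~ 0.064; binomial sds are tiny
  # at n = 10^4, so a factor-2 separation is overwhelmingly significant
  expect_gt(edges, 2 * middle)
})

test_that("tanh and mapped sigmoid forms are prediction-identical", {
  # printed mapping of the parameters: a^2 doubles, s doubles, t unchanged
  nt <- restricted_neuron(matrix(1, 1, 1), matrix(1, 1, 1),
                          matrix(0.5, 1, 1), 0.2, "tanh")
  ns <- to_sigmoid_form(nt)
  expect_equal(ns$amp_root^2, matrix(2, 1, 1))
  expect_equal(ns$slope, matrix(2, 1, 1))
  expect_equal(ns$threshold, matrix(0.5, 1, 1))

  set.seed(31)
  for (rep in 1:5) {
    nt <- random_restricted(3, 2, "tanh", seed = 310 + rep)
    ns <- to_sigmoid_form(nt)
    ps <- generate_patterns(3, 100, seed = 320 + rep)
    zt <- somatic_input(nt, ps) - nt$soma_threshold
    zs <- somatic_input(ns, ps) - ns$soma_threshold
    expect_equal(zt, zs, tolerance = 1e-10)
    expect_identical(predict(nt, ps), predict(ns, ps))
  }
  # all-zero amplitudes: both forms constant, hence equal predictions
  z0 <- restricted_neuron(matrix(0, 2, 2), matrix(1, 2, 2),
                          matrix(0.5, 2, 2), 0.1, "tanh")
  ps <- generate_patterns(2, 10, seed = 33)
  expect_identical(predict(to_sigmoid_form(z0), ps), predict(z0, ps))
  expect_error(to_sigmoid_form(to_sigmoid_form(z0)), "tanh")
})

test_that("the R and C++ training engines produce identical trajectories", {
  ps <- generate_patterns(5, 12, seed = 34)
  cfg <- train_config(max_epochs = 250, seed = 77)
  fc <- train_restricted(ps, 2, cfg, engine = "cpp")
  fr <- train_restricted(ps, 2, cfg, engine = "r")
  expect_equal(fc$neuron$amp_root, fr$neuron$amp_root, tolerance = 1e-12)
  expect_equal(fc$neuron$slope, fr$neuron$slope, tolerance = 1e-12)
  expect_equal(fc$neuron$threshold, fr$neuron$threshold, tolerance = 1e-12)
  expect_equal(fc$neuron$soma_threshold, fr$neuron$soma_threshold,
               tolerance = 1e-12)
  expect_identical(fc$success, fr$success)
  expect_identical(fc$epochs_used, fr$epochs_used)
})

test_that("training succeeds on trivial and comfortably sub-capacity tasks", {
  one <- generate_patterns(3, 1, seed = 35)
  expect_true(train_restricted(one, 1, train_config(max_epochs = 500,
                                                    seed = 1))$success)
  easy <- generate_patterns(20, 20, seed = 36)      # load 1, far below capacity
  fit <- train_restricted(easy, 2, train_config(max_epochs = 5000, seed = 2))
  expect_true(fit$success)
  expect_identical(predict(fit$neuron, easy), easy$labels)
})

test_that("training is deterministic given the config seed", {
  ps <- generate_patterns(6, 10, seed = 37)
  cfg <- train_config(max_epochs = 300, seed = 5)
  f1 <- train_restricted(ps, 2, cfg)
  f2 <- train_restricted(ps, 2, cfg)
  expect_equal(f1$neuron, f2$neuron)
  expect_identical(f1$epochs_used, f2$epochs_used)
})
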