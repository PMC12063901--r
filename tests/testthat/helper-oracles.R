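# Independent oracles used across tests. These deliberately avoid the code
# paths they certify.

# Exhaustive oracle for the per-axon staircase objective
#   -sum(w*y*I) + lambda*sum(I^2),  I nondecreasing, I[1] = 0.
# Enumerates every contiguous level-set partition of positions 1..P (2^(P-1)
# boundary choices). The first block is pinned at 0; every other block takes
# its unconstrained optimum (block mean of the targets); candidates whose
# block values are not nondecreasing-from-zero are infeasible and skipped.
# The optimum is attained by one of the feasible candidates.
envelope_oracle <- function(labels, weights, lambda) {
  P <- length(labels)
  stopifnot(P <= 14)
  u <- labels * weights
  obj <- function(I) -sum(u * I) + lambda * sum(I^2)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^(P - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(P - 2))) > 0)   # cut after position k
    starts <- c(1, cuts + 1)
    ends <- c(cuts, P)
    vals <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      vals[b] <- if (b == 1) 0 else sum(u[idx]) / (2 * lambda * length(idx))
    }
    if (any(diff(vals) < 0) || any(vals < 0)) next
    I <- rep(vals, times = ends - starts + 1)
    o <- obj(I)
    if (o < best_obj) { best_obj <- o; best <- I }
  }
  list(I = best, objective = best_obj)
}

staircase_objective <- function(I, labels, weights, lambda) {
  -sum(weights * labels * I) + lambda * sum(I^2)
}

# Stationarity certificate: each interior position has either no step or a
# vanishing tail sum of (y*w - 2*lambda*I).
kkt_certificate <- function(I, labels, weights, lambda, tol = 1e-8) {
  P <- length(I)
  resid <- labels * weights - 2 * lambda * I
  ok <- TRUE
  for (b in seq_len(P - 1)) {
    step <- I[b + 1] - I[b]
    tail_sum <- sum(resid[(b + 1):P])
    # either no step at this position, or the tail stationarity condition
    if (step > tol && abs(tail_sum) > tol) ok <- FALSE
  }
  ok
}

# Weighted-isotonic oracle via stats::isoreg (valid when inputs are untied:
# the quadratic weights are uniform, importance weights only shift targets).
isotonic_oracle <- function(labels, weights, lambda) {
  P <- length(labels)
  targets <- labels * weights / (2 * lambda)
  c(0, pmax(0, stats::isoreg(targets[-1])$yf))
}

# Brute-force somatic current: explicit double loop over axons and synapses.
somatic_bruteforce <- function(neuron, ps) {
  n <- if (neuron$param_form == "tanh") to_sigmoid_form(neuron) else neuron
  P <- nrow(ps$inputs)
  z <- numeric(P)
  for (mu in seq_len(P)) {
    for (i in seq_len(nrow(n$amp_root))) {
      for (j in seq_len(ncol(n$amp_root))) {
        z[mu] <- z[mu] + synapse_response(n$amp_root[i, j], n$slope[i, j],
                                          n$threshold[i, j], ps$inputs[mu, i])
      }
    }
  }
  z - if (neuron$param_form == "tanh") sum(neuron$amp_root^2) else 0
}

random_restricted <- function(N, M, form = "sigmoid", seed = 1) {
  set.seed(seed)
  restricted_neuron(
    matrix(runif(N * M, 0.2, 0.8), N, M),
    matrix(runif(N * M, 0.5, 8), N, M),
    matrix(runif(N * M), N, M),
    runif(1, -0.5, 0.5),
    form
  )
}

# The 4-corner XOR task: monotone additive models provably cannot solve it.
xor_patterns <- function(lo = 0.01, hi = 0.99) {
  x <- as.matrix(expand.grid(c(lo, hi), c(lo, hi)))
  colnames(x) <- NULL
  y <- ifelse(xor(x[, 1] > 0.5, x[, 2] > 0.5), 1, -1)
  pattern_set(x, y)
}

# Central finite-difference gradient of the hinge loss wrt one parameter.
fd_gradient <- function(neuron, ps, field, idx, margin, h = 1e-6) {
  loss_at <- function(v) {
    n2 <- neuron
    if (field == "soma_threshold") n2$soma_threshold <- v else n2[[field]][idx] <- v
    hinge_loss(somatic_input(n2, ps), ps$labels, n2$soma_threshold, margin)
  }
  v0 <- if (field == "soma_threshold") neuron$soma_threshold else neuron[[field]][idx]
  (loss_at(v0 + h) - loss_at(v0 - h)) / (2 * h)
}
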