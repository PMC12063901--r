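#' Unrestricted parallel-synapse neuron: monotone staircase axons
#'
#' In the limit of unlimited parallel synapses per axon, the aggregate
#' transmission function of an axon becomes an arbitrary monotone
#' nondecreasing function. On a dataset of P patterns it can take at most P
#' distinct values, so it is parameterized as a nonnegative nondecreasing
#' staircase over the axon's sorted input values, with the first value pinned
#' at zero (an overall offset is absorbed by the somatic threshold). Tied
#' input values necessarily share one transmission value.
#'
#' @name staircase
NULL

staircase_axon <- function(sorted_inputs, order, values) {
  stopifnot(length(sorted_inputs) == length(values),
            length(order) == length(values))
  if (is.unsorted(sorted_inputs)) stop("breakpoints must be nondecreasing")
  if (is.unsorted(values)) stop("staircase values must be nondecreasing")
  if (length(values) && values[1] != 0) stop("first staircase value must be 0")
  structure(
    list(sorted_inputs = sorted_inputs, order = as.integer(order),
         values = values),
    class = "staircase_axon"
  )
}

staircase_model <- function(axons, soma_threshold, lambda, weights = NULL,
                            iterations = NA_integer_) {
  structure(
    list(axons = axons, soma_threshold = as.numeric(soma_threshold),
         lambda = lambda, weights = weights, iterations = as.integer(iterations)),
    class = "staircase_model"
  )
}

#' @export
print.staircase_model <- function(x, ...) {
  cat(sprintf(
    "<staircase_model> N = %d axons, P = %d breakpoints/axon, theta = %.4g, lambda = %.3g\n",
    length(x$axons), length(x$axons[[1]]$values), x$soma_threshold, x$lambda
  ))
  invisible(x)
}

#' Envelope solver for one axon's staircase
#'
#' Minimizes `-sum(w * y * I) + lambda * sum(I^2)` over nonnegative
#' nondecreasing sequences `I` with `I[1] = 0`, where labels and weights are
#' given in the axon's sorted-input order. Completing the square shows this is
#' a weighted isotonic regression of the targets `y*w/(2*lambda)` (positions
#' 2..P; position 1 is pinned), clipped at zero. It is solved by one
#' left-to-right pool-adjacent-violators pass, the algebraic equivalent of
#' taking the greatest convex minorant of the cumulative weighted-label walk
#' `S[k] = sum(y*w, up to k)` and reading step values off its positive
#' segment slopes divided by `2*lambda`.
#'
#' @param labels +1/-1 vector, length P, in sorted-input order.
#' @param weights positive importance weights, length P.
#' @param lambda positive L2 penalty on the staircase values.
#' @param groups optional nondecreasing integer group ids marking tied inputs
#'   (tied positions must share one transmission value and pool their
#'   label-weight contributions); default: every position its own group.
#' @return Nonnegative nondecreasing numeric vector of length P with first
#'   element 0.
#' @examples
#' envelope_solve(c(-1, 1, 1), c(1, 2, 1), lambda = 0.5)  # 0, 1.5, 1.5
#' @export
envelope_solve <- function(labels, weights, lambda, groups = NULL) {
  P <- length(labels)
  if (length(weights) != P) stop("labels and weights must have equal length")
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0) {
    stop("`lambda` must be a positive scalar")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(groups)) groups <- seq_len(P)
  if (is.unsorted(groups)) stop("`groups` must be nondecreasing")
  if (P == 0) return(numeric(0))

  gid <- cumsum(c(TRUE, diff(groups) != 0))    # normalize ids to 1..G
  u <- labels * weights
  gsum <- as.vector(rowsum(u, gid))            # per-group walk increment
  gcnt <- tabulate(gid)                        # per-group multiplicity
  G <- length(gcnt)
  if (G == 1) return(rep(0, P))

  # PAVA over groups 2..G: block means are segment slopes of the greatest
  # convex minorant of the cumulative walk; group 1 is pinned at I = 0 and
  # its walk increment never enters any stationarity sum.
  nblk <- 0L
  bsum <- numeric(G); bcnt <- numeric(G)       # block walk-sum and pattern width
  bng <- integer(G)                            # groups absorbed per block
  for (g in 2:G) {
    nblk <- nblk + 1L
    bsum[nblk] <- gsum[g]; bcnt[nblk] <- gcnt[g]; bng[nblk] <- 1L
    while (nblk > 1L &&
           bsum[nblk] * bcnt[nblk - 1L] <= bsum[nblk - 1L] * bcnt[nblk]) {
      bsum[nblk - 1L] <- bsum[nblk - 1L] + bsum[nblk]
      bcnt[nblk - 1L] <- bcnt[nblk - 1L] + bcnt[nblk]
      bng[nblk - 1L] <- bng[nblk - 1L] + bng[nblk]
      nblk <- nblk - 1L
    }
  }
  lev <- pmax(0, bsum[seq_len(nblk)] / (2 * lambda * bcnt[seq_len(nblk)]))
  gval <- c(0, rep(lev, times = bng[seq_len(nblk)]))
  gval[gid]
}

#' Evaluate a staircase axon at arbitrary inputs
#'
#' Right-continuous step interpolation: the value at `x` is the staircase
#' value at the largest breakpoint `<= x`; zero below the smallest
#' breakpoint; the top value above the largest. Evaluating at a training
#' input reproduces its fitted value exactly.
#'
#' @param axon a `staircase_axon` (element of a trained model's `axons`).
#' @param x numeric input(s).
#' @return Numeric vector of transmission values.
#' @export
axon_transmission <- function(axon, x) {
  stopifnot(inherits(axon, "staircase_axon"))
  idx <- findInterval(x, axon$sorted_inputs)
  out <- numeric(length(x))
  out[idx > 0] <- axon$values[idx[idx > 0]]
  out
}

#' Predict labels with a staircase model
#'
#' `sign(sum_i I_i(x_i) - theta)` with the tie mapped to -1.
#'
#' @param object a `staircase_model`.
#' @param ps a [pattern_set].
#' @param ... unused.
#' @return Vector of +1/-1 predictions.
#' @export
predict.staircase_model <- function(object, ps, ...) {
  z <- staircase_somatic(object, ps$inputs)
  ifelse(z - object$soma_threshold > 0, 1, -1)
}

staircase_somatic <- function(model, X) {
  z <- numeric(nrow(X))
  for (i in seq_along(model$axons)) {
    z <- z + axon_transmission(model$axons[[i]], X[, i])
  }
  z
}

# Deterministic threshold scan: candidates are below the minimum somatic sum,
# midpoints between consecutive distinct sums, and the maximum sum (all -1);
# pick the candidate with fewest misclassifications, ties toward smaller theta.
scan_threshold <- function(z, labels) {
  d <- sort(unique(z))
  cand <- c(d[1] - 1, if (length(d) > 1) (d[-length(d)] + d[-1]) / 2, d[length(d)])
  errs <- vapply(cand, function(th) {
    pred <- ifelse(z - th > 0, 1, -1)
    sum(pred != labels)
  }, numeric(1))
  cand[which.min(errs)]
}

#' Train the unrestricted neuron by iterative envelope reweighting
#'
#' Each iteration solves the per-axon envelope problem independently for
#' every axon under the shared importance weights (all initialized to one),
#' sets the somatic threshold by a deterministic 1-D scan minimizing the
#' number of misclassifications, evaluates the predictions, and increments
#' the weight of every misclassified pattern by one. Iteration stops when all
#' patterns are correct or the budget is exhausted.
#'
#' @param ps a [pattern_set].
#' @param lambda positive L2 penalty; default 1/2 maps unit-weight labels to
#'   unit-scale currents.
#' @param max_iter reweighting iterations budget, default 1000.
#' @return A list: `model` (a `staircase_model`, including final weights),
#'   `success`, `iterations_used`, `weights` (final importance weights, in
#'   pattern order).
#' @examples
#' ps <- pattern_set(matrix(c(0.2, 0.8)), c(-1, 1))
#' train_unrestricted(ps, lambda = 0.5)$success
#' @export
train_unrestricted <- function(ps, lambda = 0.5, max_iter = 1000L) {
  stopifnot(inherits(ps, "pattern_set"), max_iter >= 1)
  X <- ps$inputs; y <- ps$labels
  P <- nrow(X); N <- ncol(X)
  orders <- lapply(seq_len(N), function(i) order(X[, i]))
  sorted_x <- lapply(seq_len(N), function(i) X[orders[[i]], i])
  groups <- lapply(sorted_x, function(sx) cumsum(c(TRUE, diff(sx) > 0)))
  w <- rep(1, P)

  success <- FALSE
  iterations_used <- 0L
  axons <- vector("list", N)
  theta <- 0
  for (iter in seq_len(max_iter)) {
    z <- numeric(P)
    for (i in seq_len(N)) {
      ord <- orders[[i]]
      I <- envelope_solve(y[ord], w[ord], lambda, groups[[i]])
      axons[[i]] <- staircase_axon(sorted_x[[i]], ord, I)
      z[ord] <- z[ord] + I
    }
    theta <- scan_threshold(z, y)
    pred <- ifelse(z - theta > 0, 1, -1)
    wrong <- pred != y
    iterations_used <- iter
    if (!any(wrong)) {
      success <- TRUE
      break
    }
    w[wrong] <- w[wrong] + 1
  }
  model <- staircase_model(axons, theta, lambda, weights = w,
                           iterations = iterations_used)
  list(model = model, success = success, iterations_used = iterations_used,
       weights = w)
}

#' Count effective synapses on a staircase axon
#'
#' Step increments `diff(values)` strictly larger than `ratio` times the
#' axon's maximum step increment count as distinct effective synapses; an
#' all-flat axon has none.
#'
#' @param axon a `staircase_axon`, or a numeric vector of step increments.
#' @param ratio relative amplitude cut, default 1/1000.
#' @return Nonnegative integer count.
#' @export
effective_synapse_count <- function(axon, ratio = 1 / 1000) {
  stopifnot(ratio > 0, ratio < 1)
  steps <- if (inherits(axon, "staircase_axon")) diff(axon$values) else as.numeric(axon)
  if (length(steps) == 0) return(0L)
  mx <- max(steps)
  if (mx <= 0) return(0L)
  sum(steps > ratio * mx)
}
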