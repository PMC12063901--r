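#' Sign-constrained perceptron baseline
#'
#' The comparison model for capacity experiments: a neuron with a single
#' linear synapse of nonnegative efficacy per axon and a step somatic
#' nonlinearity, i.e. a perceptron whose weights are constrained to the
#' nonnegative orthant (all-excitatory synapses, per Dale's law). Its
#' asymptotic classification capacity on random patterns is P*/N = 1.
#'
#' Training is the classical online margin-perceptron rule: patterns are
#' visited cyclically, and each margin violation `y*(w.x - theta) <= margin`
#' triggers `w <- pmax(w + eta*y*x, 0)` (projection onto the nonnegative
#' orthant after every update) and `theta <- theta - eta*y`. Success means
#' all P patterns strictly correct (`y*(w.x - theta) > 0`) at the end of an
#' epoch.
#'
#' @param ps a [pattern_set].
#' @param max_epochs epoch budget, default 5000.
#' @param margin required functional margin during training; default 0 (plain
#'   perceptron updates).
#' @param eta learning rate, default 0.01.
#' @param seed seed for the (uniform, nonnegative) weight initialization.
#' @return A list: `model` (class `sign_perceptron` with fields `weights`,
#'   `bias_threshold`, `margin`), `success`, `epochs_used`.
#' @examples
#' ps <- generate_patterns(20, 8, seed = 2)  # load well below capacity 1
#' train_perceptron(ps, max_epochs = 500)$success
#' @export
train_perceptron <- function(ps, max_epochs = 5000L, margin = 0, eta = 0.01,
                             seed = 0L) {
  stopifnot(inherits(ps, "pattern_set"), max_epochs >= 1, margin >= 0, eta > 0)
  X <- ps$inputs; y <- ps$labels
  N <- ncol(X)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  w <- stats::runif(N, 0, 0.1)
  theta <- sum(w) * mean(X)   # start near the center of the somatic range

  res <- cpp_train_perceptron(X, y, w, theta, margin, eta,
                              as.integer(max_epochs))
  model <- structure(
    list(weights = res$weights, bias_threshold = res$theta, margin = margin),
    class = "sign_perceptron"
  )
  list(model = model, success = res$success, epochs_used = res$epochs_used)
}

#' @export
predict.sign_perceptron <- function(object, ps, ...) {
  z <- as.vector(ps$inputs %*% object$weights) - object$bias_threshold
  ifelse(z > 0, 1, -1)
}

#' Theoretical sign-constrained perceptron capacity
#'
#' The asymptotic reference value P*/N = 1 for large N, used in reports and
#' plots. For very small N the asymptotic value is a poor guide; the result
#' carries a `finite_n_caveat` attribute when N < 10.
#'
#' @param N number of axons.
#' @return 1.0 (with attribute `finite_n_caveat` for small N).
#' @export
perceptron_capacity_reference <- function(N) {
  stopifnot(N >= 1)
  out <- 1.0
  if (N < 10) attr(out, "finite_n_caveat") <- TRUE
  out
}
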