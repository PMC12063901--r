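#' Restricted parallel-synapse neuron
#'
#' The restricted neuron connects each of N presynaptic axons to the soma
#' through a fixed number M of parallel synapses. Each synapse transmits a
#' sigmoidal function of its axonal input with three learnable parameters:
#' an amplitude root `a` (the transmitted current saturates at `a^2`, squared
#' so the amplitude can never become negative during learning), a nonnegative
#' slope `s`, and a threshold `t` at which the response rises fastest. The
#' somatic current is the plain sum over all N*M synapses — there are no
#' dendritic nonlinearities — and the neuron fires (+1) when the current
#' exceeds the somatic threshold `theta`.
#'
#' Two algebraically equivalent parameterizations are supported. In
#' `"sigmoid"` form a synapse responds with `a^2 * sigmoid(s*(x - t))`; in
#' `"tanh"` form with `a^2 * tanh(s*(x - t))`, i.e.
#' `2 a^2 sigmoid(2s(x - t)) - a^2`, which is centered around zero and makes
#' the somatic threshold slightly easier to learn. [to_sigmoid_form()] maps a
#' tanh-form neuron to the prediction-identical sigmoid-form neuron.
#'
#' @param amp_root numeric N x M matrix of amplitude roots `a[i,j]`.
#' @param slope numeric N x M matrix of nonnegative slopes `s[i,j]`.
#' @param threshold numeric N x M matrix of thresholds `t[i,j]`.
#' @param soma_threshold scalar somatic threshold `theta`.
#' @param param_form `"sigmoid"` or `"tanh"`.
#' @return An object of class `restricted_neuron`.
#' @export
restricted_neuron <- function(amp_root, slope, threshold, soma_threshold,
                              param_form = c("sigmoid", "tanh")) {
  param_form <- match.arg(param_form)
  amp_root <- as.matrix(amp_root); slope <- as.matrix(slope)
  threshold <- as.matrix(threshold)
  if (!all(dim(amp_root) == dim(slope)) || !all(dim(amp_root) == dim(threshold))) {
    stop("amp_root, slope and threshold must share the same N x M shape")
  }
  if (any(slope < 0)) stop("slopes must be nonnegative (monotone, excitatory synapses)")
  structure(
    list(amp_root = amp_root, slope = slope, threshold = threshold,
         soma_threshold = as.numeric(soma_threshold), param_form = param_form),
    class = "restricted_neuron"
  )
}

#' @export
print.restricted_neuron <- function(x, ...) {
  cat(sprintf(
    "<restricted_neuron> N = %d axons x M = %d synapses (%s form), theta = %.4g\n",
    nrow(x$amp_root), ncol(x$amp_root), x$param_form, x$soma_threshold
  ))
  invisible(x)
}

sigmoid <- function(u) 1 / (1 + exp(-u))

#' Single-synapse transmission function
#'
#' The current contributed by one synapse with amplitude root `a`, slope `s`
#' and threshold `t` at input `x`: `a^2 * sigmoid(s * (x - t))`. The response
#' lies in `[0, a^2]` and is nondecreasing in `x`.
#'
#' @param a amplitude root (effective amplitude is `a^2`).
#' @param s slope, must be `>= 0`.
#' @param t threshold.
#' @param x input value(s); vectorized.
#' @return Synaptic response, same length as `x`.
#' @examples
#' synapse_response(1, 5, 0.5, 0.5)  # sigmoid at threshold: 0.5
#' @export
synapse_response <- function(a, s, t, x) {
  if (any(s < 0)) stop("slope `s` must be nonnegative")
  a^2 * sigmoid(s * (x - t))
}

# Per-synapse response matrix: P x (N*M), columns in column-major (i, j)
# order of the N x M parameter matrices, for either parameter form.
response_matrix <- function(neuron, X) {
  N <- nrow(neuron$amp_root); M <- ncol(neuron$amp_root)
  Xrep <- X[, rep(seq_len(N), times = M), drop = FALSE]
  a <- rep(as.vector(neuron$amp_root), each = nrow(X))
  s <- rep(as.vector(neuron$slope), each = nrow(X))
  t <- rep(as.vector(neuron$threshold), each = nrow(X))
  if (neuron$param_form == "sigmoid") {
    h <- a^2 * sigmoid(s * (Xrep - t))
  } else {
    h <- 2 * a^2 * sigmoid(2 * s * (Xrep - t)) - a^2
  }
  matrix(h, nrow = nrow(X))
}

#' Total somatic current
#'
#' Sums the responses of all N*M synapses for every pattern:
#' `z[mu] = sum_i sum_j h[i,j](x[i, mu])`. Synapses interact only through this
#' sum (and the somatic nonlinearity); there is no cross-axon interaction.
#'
#' @param neuron a [restricted_neuron].
#' @param ps a [pattern_set] with matching N.
#' @return Numeric vector of length P.
#' @export
somatic_input <- function(neuron, ps) {
  stopifnot(inherits(neuron, "restricted_neuron"), inherits(ps, "pattern_set"))
  if (ncol(ps$inputs) != nrow(neuron$amp_root)) {
    stop("neuron and pattern set disagree on the number of axons N")
  }
  rowSums(response_matrix(neuron, ps$inputs))
}

#' Predict labels with a restricted neuron
#'
#' `sign(z - theta)`, with the tie `z == theta` mapped to -1 so predictions
#' are deterministic.
#'
#' @param object a [restricted_neuron].
#' @param ps a [pattern_set].
#' @param ... unused.
#' @return Vector of +1/-1 predictions, length P.
#' @export
predict.restricted_neuron <- function(object, ps, ...) {
  z <- somatic_input(object, ps)
  ifelse(z - object$soma_threshold > 0, 1, -1)
}

#' Hinge loss of a somatic-current vector
#'
#' `L = sum_mu max(0, margin - (z[mu] - theta) * y[mu])`: zero exactly when
#' every pattern is classified correctly with margin at least `margin`.
#'
#' @param z somatic currents, length P.
#' @param labels +1/-1 labels, length P.
#' @param theta somatic threshold.
#' @param margin hinge margin epsilon (> 0 for training; the paper-default is 0.1).
#' @return Nonnegative scalar.
#' @export
hinge_loss <- function(z, labels, theta, margin) {
  if (length(z) != length(labels)) stop("`z` and `labels` must have equal length")
  sum(pmax(0, margin - (z - theta) * labels))
}

#' Margin-violating pattern set
#'
#' Indices `mu` with `margin - (z - theta) * y > 0` (strict): misclassified
#' patterns plus those correct by less than the margin. These are the
#' patterns that drive the gradient update.
#'
#' @inheritParams hinge_loss
#' @return Integer vector of indices (possibly empty).
#' @export
violating_set <- function(z, labels, theta, margin) {
  if (length(z) != length(labels)) stop("`z` and `labels` must have equal length")
  which(margin - (z - theta) * labels > 0)
}

#' Training configuration for the restricted neuron
#'
#' The update rule sums gradients over the violating set, so a stable step
#' size must shrink with the problem size: by default the four learning
#' rates are `c(0.05, 0.5, 0.15, 0.05) / P` for amplitude roots, slopes,
#' thresholds and the somatic threshold (set when training starts and P is
#' known). Slopes learn faster because their gradient carries an extra
#' factor of the (small) squared amplitude and would otherwise barely move;
#' constant rates of order 0.01 make the amplitude dynamics oscillate
#' without converging for P beyond a few dozen. Pass explicit rates to
#' override.
#'
#' @param margin hinge margin epsilon, default 0.1.
#' @param eta_a,eta_s,eta_t,eta_theta learning rates; `NULL` (default) means
#'   the 1/P-scaled defaults above.
#' @param max_epochs full-batch gradient epochs budget, default 10000
#'   (capacity protocols near the critical load typically need more; the
#'   capacity helpers pass their own budget).
#' @param resurrection_period epochs between synapse-resurrection sweeps,
#'   default 100.
#' @param amp_floor minimum amplitude restored to near-dead synapses,
#'   default 0.01.
#' @param seed integer seed controlling initialization and resurrection draws.
#' @return A list of class `train_config`.
#' @export
train_config <- function(margin = 0.1,
                         eta_a = NULL, eta_s = NULL, eta_t = NULL,
                         eta_theta = NULL,
                         max_epochs = 10000L, resurrection_period = 100L,
                         amp_floor = 0.01, seed = 0L) {
  for (eta in list(eta_a, eta_s, eta_t, eta_theta)) {
    stopifnot(is.null(eta) || eta > 0)
  }
  stopifnot(margin > 0, max_epochs >= 1, resurrection_period >= 1,
            amp_floor > 0)
  structure(
    list(margin = margin, eta_a = eta_a, eta_s = eta_s, eta_t = eta_t,
         eta_theta = eta_theta, max_epochs = as.integer(max_epochs),
         resurrection_period = as.integer(resurrection_period),
         amp_floor = amp_floor, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Fill in 1/P-scaled default learning rates once the problem size is known.
resolve_rates <- function(cfg, P) {
  defaults <- c(0.05, 0.5, 0.15, 0.05) / P
  if (is.null(cfg$eta_a)) cfg$eta_a <- defaults[1]
  if (is.null(cfg$eta_s)) cfg$eta_s <- defaults[2]
  if (is.null(cfg$eta_t)) cfg$eta_t <- defaults[3]
  if (is.null(cfg$eta_theta)) cfg$eta_theta <- defaults[4]
  cfg
}

#' One full-batch gradient epoch
#'
#' Applies the four hinge-loss gradient updates (amplitude root, slope,
#' threshold, somatic threshold) simultaneously, all evaluated at the
#' pre-update parameters over the margin-violating set; slopes are clipped at
#' zero afterwards to preserve monotonicity. An empty violating set returns
#' the neuron unchanged.
#'
#' @param neuron a [restricted_neuron] (either parameter form).
#' @param ps a [pattern_set].
#' @param cfg a [train_config].
#' @return The updated [restricted_neuron].
#' @export
gradient_step <- function(neuron, ps, cfg) {
  stopifnot(inherits(neuron, "restricted_neuron"), inherits(ps, "pattern_set"))
  N <- nrow(neuron$amp_root); M <- ncol(neuron$amp_root)
  if (ncol(ps$inputs) != N) stop("neuron and pattern set disagree on N")
  cfg <- resolve_rates(cfg, nrow(ps$inputs))
  z <- somatic_input(neuron, ps)
  omega <- violating_set(z, ps$labels, neuron$soma_threshold, cfg$margin)
  if (length(omega) == 0) return(neuron)

  X <- ps$inputs[omega, , drop = FALSE]
  y <- ps$labels[omega]
  P <- length(omega)
  Xrep <- X[, rep(seq_len(N), times = M), drop = FALSE]
  a <- neuron$amp_root; s <- neuron$slope; t <- neuron$threshold
  sv <- rep(as.vector(s), each = P)
  tv <- rep(as.vector(t), each = P)
  dx <- Xrep - tv

  if (neuron$param_form == "sigmoid") {
    sig <- sigmoid(sv * dx)
    # S1 = sum_y sigma; S2 = sum_y sigma(1-sigma)(x-t); S3 = sum_y sigma(1-sigma)
    S1 <- matrix(colSums(y * sig), N, M)
    S2 <- matrix(colSums(y * sig * (1 - sig) * dx), N, M)
    S3 <- matrix(colSums(y * sig * (1 - sig)), N, M)
    a_new <- a + cfg$eta_a * 2 * a * S1
    s_new <- s + cfg$eta_s * a^2 * S2
    t_new <- t - cfg$eta_t * a^2 * s * S3
  } else {
    sig <- sigmoid(2 * sv * dx)
    S1 <- matrix(colSums(y * (2 * sig - 1)), N, M)
    S2 <- matrix(colSums(y * sig * (1 - sig) * dx), N, M)
    S3 <- matrix(colSums(y * sig * (1 - sig)), N, M)
    a_new <- a + cfg$eta_a * 2 * a * S1
    s_new <- s + cfg$eta_s * 4 * a^2 * S2
    t_new <- t - cfg$eta_t * 4 * a^2 * s * S3
  }
  theta_new <- neuron$soma_threshold - cfg$eta_theta * sum(y)
  s_new[s_new < 0] <- 0
  restricted_neuron(a_new, s_new, t_new, theta_new, neuron$param_form)
}

#' Resurrect ineffective synapses
#'
#' During training some synapses' amplitudes shrink towards zero, which makes
#' all their gradients vanish; they become permanently ineffective. The
#' resurrection sweep restores every synapse whose amplitude `a^2` has fallen
#' below `amp_floor` to exactly `amp_floor` and redraws its threshold from an
#' edge-biased distribution over the input range — a Beta(1/2, 1/2) law
#' rescaled to the range, U-shaped like the threshold distribution that
#' training itself discovers. Other synapses are untouched.
#'
#' @param neuron a [restricted_neuron].
#' @param amp_floor positive amplitude floor (default 0.01).
#' @param input_range length-2 numeric range the thresholds live on.
#' @param seed optional seed; `NULL` (default) draws from the current RNG
#'   stream, which is what the training loop uses.
#' @return The repaired [restricted_neuron].
#' @export
resurrect_synapses <- function(neuron, amp_floor = 0.01, input_range = c(0, 1),
                               seed = NULL) {
  stopifnot(amp_floor > 0, length(input_range) == 2)
  if (!(input_range[2] > input_range[1])) stop("empty input range")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  flagged <- which(neuron$amp_root^2 < amp_floor)
  if (length(flagged) == 0) return(neuron)
  a <- neuron$amp_root; t <- neuron$threshold
  a[flagged] <- sqrt(amp_floor)
  t[flagged] <- input_range[1] +
    (input_range[2] - input_range[1]) * stats::rbeta(length(flagged), 0.5, 0.5)
  restricted_neuron(a, neuron$slope, t, neuron$soma_threshold, neuron$param_form)
}

#' Map a tanh-form neuron to its sigmoid-form twin
#'
#' Uses `tanh(u) = 2*sigmoid(2u) - 1`: amplitudes double (`a^2 = 2 a'^2`),
#' slopes double (`s = 2 s'`), thresholds carry over, and the somatic
#' threshold absorbs the centering offset, `theta = theta' + sum(a'^2)`, so
#' that `z - theta` is preserved exactly and predictions are identical on
#' every input.
#'
#' @param neuron a [restricted_neuron] with `param_form == "tanh"`.
#' @return The equivalent sigmoid-form [restricted_neuron].
#' @export
to_sigmoid_form <- function(neuron) {
  stopifnot(inherits(neuron, "restricted_neuron"))
  if (neuron$param_form != "tanh") stop("`neuron` must be in tanh form")
  restricted_neuron(
    amp_root = sqrt(2) * abs(neuron$amp_root),
    slope = 2 * neuron$slope,
    threshold = neuron$threshold,
    soma_threshold = neuron$soma_threshold + sum(neuron$amp_root^2),
    param_form = "sigmoid"
  )
}

# Random initialization of a restricted neuron over a given input range.
# Amplitude roots away from zero avoid dead starts; slopes of order 1-10 put
# sigmoid transitions at the scale of the input range; thresholds uniform over
# the range. The somatic threshold starts at the mean somatic current: half
# the total amplitude for the sigmoid form, zero for the centered tanh form.
init_restricted <- function(N, M, input_range, param_form) {
  a <- matrix(stats::runif(N * M, 0.1, 0.5), N, M)
  s <- matrix(stats::runif(N * M, 1, 10), N, M)
  t <- matrix(stats::runif(N * M, input_range[1], input_range[2]), N, M)
  theta <- if (param_form == "sigmoid") sum(a^2) / 2 else 0
  restricted_neuron(a, s, t, theta, param_form)
}

#' Train a restricted neuron by hinge-loss gradient descent
#'
#' Full-batch gradient epochs (see [gradient_step()]) until every pattern is
#' classified strictly correctly (`(z - theta) * y > 0`) or the epoch budget
#' is exhausted, with a synapse-resurrection sweep every
#' `resurrection_period` epochs. Training uses the margin `cfg$margin` to
#' build the update set, but success is strict correctness of all P patterns.
#' The whole trajectory is deterministic given `cfg$seed`.
#'
#' @param ps a [pattern_set].
#' @param M number of parallel synapses per axon, >= 1.
#' @param cfg a [train_config].
#' @param param_form parameterization used during training; the centered
#'   `"tanh"` form (default) learns the somatic threshold more easily.
#' @param engine `"cpp"` (fast compiled loop, default) or `"r"` (reference
#'   loop built from [gradient_step()] and [resurrect_synapses()]; identical
#'   trajectory).
#' @return A list: `neuron` (in the training form), `success` (all P patterns
#'   strictly correct at termination), `epochs_used`.
#' @examples
#' ps <- generate_patterns(10, 8, seed = 1)
#' fit <- train_restricted(ps, M = 2, train_config(max_epochs = 2000, seed = 1))
#' fit$success
#' @export
train_restricted <- function(ps, M, cfg = train_config(),
                             param_form = c("tanh", "sigmoid"),
                             engine = c("cpp", "r")) {
  stopifnot(inherits(ps, "pattern_set"), M >= 1)
  param_form <- match.arg(param_form)
  engine <- match.arg(engine)
  N <- ncol(ps$inputs)
  cfg <- resolve_rates(cfg, nrow(ps$inputs))
  input_range <- range(ps$inputs)
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old), add = TRUE)
  neuron <- init_restricted(N, as.integer(M), input_range, param_form)

  if (engine == "cpp") {
    res <- cpp_train_restricted(
      ps$inputs, ps$labels,
      neuron$amp_root, neuron$slope, neuron$threshold, neuron$soma_threshold,
      param_form == "tanh", cfg$margin,
      c(cfg$eta_a, cfg$eta_s, cfg$eta_t, cfg$eta_theta),
      cfg$max_epochs, cfg$resurrection_period, cfg$amp_floor,
      input_range[1], input_range[2]
    )
    neuron <- restricted_neuron(res$amp_root, res$slope, res$threshold,
                                res$theta, param_form)
    return(list(neuron = neuron, success = res$success,
                epochs_used = res$epochs_used))
  }

  epochs_used <- 0L
  success <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    z <- somatic_input(neuron, ps)
    margins <- (z - neuron$soma_threshold) * ps$labels
    if (isTRUE(all(margins > 0))) {
      success <- TRUE
      break
    }
    # no violators yet not all strictly correct: non-finite parameters
    # (divergence) or a zero-margin tie; no update can change anything
    if (!any(cfg$margin - margins > 0, na.rm = TRUE)) break
    neuron <- gradient_step(neuron, ps, cfg)
    epochs_used <- epoch
    if (epoch %% cfg$resurrection_period == 0) {
      neuron <- resurrect_synapses(neuron, cfg$amp_floor, input_range)
    }
  }
  if (!success) {
    z <- somatic_input(neuron, ps)
    success <- isTRUE(all((z - neuron$soma_threshold) * ps$labels > 0))
  }
  list(neuron = neuron, success = success, epochs_used = epochs_used)
}
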