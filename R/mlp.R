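#' Feedforward network with a parallel-synapse output layer
#'
#' A two-layer fully connected classifier in which each hidden neuron
#' connects to each output neuron through M parallel sigmoidal synapses (the
#' same parameterization as the restricted neuron, applied to the hidden
#' activation), or — for the parameter-matched comparison network — through a
#' single linear synapse constrained to a nonnegative weight. Input-to-hidden
#' connections are ordinary linear synapses; hidden units use the Softplus
#' smooth rectifier; inputs are standardized with training-set statistics
#' before the hidden layer. Training minimizes multi-class cross-entropy with
#' an adaptive-moment optimizer, re-projecting slopes (parallel mode) or
#' hidden-to-output weights (linear mode) onto the nonnegative orthant after
#' every step so the hidden-to-output mapping stays coordinatewise monotone.
#'
#' @param d_in input dimension (default 784, a 28x28 image).
#' @param d_hidden hidden-layer width.
#' @param d_out number of classes (default 10).
#' @param synapse_mode `"parallel"` or `"linear_nonneg"`.
#' @param M parallel synapses per hidden-to-output connection (parallel mode).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(d_in = 784L, d_hidden, d_out = 10L,
                         synapse_mode = c("parallel", "linear_nonneg"),
                         M = 3L) {
  synapse_mode <- match.arg(synapse_mode)
  stopifnot(d_in >= 1, d_hidden >= 1, d_out >= 1, M >= 1)
  structure(
    list(d_in = as.integer(d_in), d_hidden = as.integer(d_hidden),
         d_out = as.integer(d_out), synapse_mode = synapse_mode,
         M = as.integer(M)),
    class = "network_spec"
  )
}

#' Learnable parameter count of a network spec
#'
#' Closed forms including all bias terms: parallel mode has
#' `(d_in + 1) d_hidden + (3 M d_hidden + 1) d_out` parameters (three
#' parameters per synapse); linear mode has
#' `(d_in + 1) d_hidden + (d_hidden + 1) d_out`. At equal `d_hidden` the
#' parallel net carries `d_hidden * d_out * (3M - 1)` extra parameters.
#'
#' @param spec a [network_spec].
#' @return Integer parameter count.
#' @examples
#' count_parameters(network_spec(784, 20, 10, "parallel", M = 3))   # 17510
#' count_parameters(network_spec(784, 22, 10, "linear_nonneg"))     # 17500
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with(spec, {
    if (synapse_mode == "parallel") {
      (d_in + 1L) * d_hidden + (3L * M * d_hidden + 1L) * d_out
    } else {
      (d_in + 1L) * d_hidden + (d_hidden + 1L) * d_out
    }
  })
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Build a network with random initial parameters
#'
#' @param spec a [network_spec].
#' @param seed integer seed; initialization is deterministic given the seed.
#' @return An object of class `parallel_net`.
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dh <- spec$d_hidden; dout <- spec$d_out; din <- spec$d_in
  net <- list(
    spec = spec,
    W1 = matrix(stats::rnorm(din * dh, 0, 1 / sqrt(din)), din, dh),
    b1 = numeric(dh),
    b2 = numeric(dout),
    center = numeric(din), scale = rep(1, din)
  )
  if (spec$synapse_mode == "parallel") {
    M <- spec$M
    net$A <- array(stats::runif(dh * dout * M, 0.1, 0.5), c(dh, dout, M))
    net$S <- array(stats::runif(dh * dout * M, 0.5, 2), c(dh, dout, M))
    net$T <- array(stats::runif(dh * dout * M, 0, 2), c(dh, dout, M))
  } else {
    net$W2 <- matrix(stats::runif(dh * dout, 0, 1 / sqrt(dh)), dh, dout)
  }
  structure(net, class = "parallel_net")
}

#' @export
print.parallel_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<parallel_net> %d-%d-%d, mode = %s%s, %d parameters\n",
              s$d_in, s$d_hidden, s$d_out, s$synapse_mode,
              if (s$synapse_mode == "parallel") sprintf(" (M = %d)", s$M) else "",
              count_parameters(s)))
  invisible(x)
}

# enumeration of learnable values actually stored in a built network
enumerate_parameters <- function(net) {
  n <- length(net$W1) + length(net$b1) + length(net$b2)
  if (net$spec$synapse_mode == "parallel") {
    n + length(net$A) + length(net$S) + length(net$T)
  } else {
    n + length(net$W2)
  }
}

# Full forward pass keeping intermediates for backprop.
forward_full <- function(net, X) {
  Xn <- sweep(sweep(X, 2, net$center), 2, net$scale, "/")
  H0 <- sweep(Xn %*% net$W1, 2, net$b1, "+")
  H <- softplus(H0)
  B <- nrow(X)
  scores <- matrix(rep(net$b2, each = B), B, net$spec$d_out)
  if (net$spec$synapse_mode == "parallel") {
    for (o in seq_len(net$spec$d_out)) {
      for (m in seq_len(net$spec$M)) {
        a2 <- net$A[, o, m]^2
        D <- sweep(H, 2, net$T[, o, m])
        sig <- 1 / (1 + exp(-sweep(D, 2, net$S[, o, m], "*")))
        scores[, o] <- scores[, o] + as.vector(sig %*% a2)
      }
    }
  } else {
    scores <- scores + H %*% net$W2
  }
  list(Xn = Xn, H0 = H0, H = H, scores = scores)
}

#' Forward pass: class scores for a batch
#'
#' @param net a built [build_network()] network.
#' @param X numeric matrix, batch x d_in.
#' @return Matrix of raw class scores, batch x d_out (softmax is implicit in
#'   the training loss).
#' @export
forward <- function(net, X) {
  stopifnot(inherits(net, "parallel_net"))
  X <- as.matrix(X)
  if (ncol(X) != net$spec$d_in) stop("input has wrong dimension")
  if (nrow(X) == 0) stop("batch must be nonempty")
  forward_full(net, X)$scores
}

#' @export
predict.parallel_net <- function(object, X, ...) {
  max.col(forward(object, as.matrix(X)), ties.method = "first") - 1L
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Train a network on labeled vectors/images
#'
#' Minimizes multi-class cross-entropy by mini-batch adaptive-moment descent.
#' After every optimizer step slopes (parallel mode) or hidden-to-output
#' weights (linear mode) are clipped at zero, so the monotonicity constraint
#' holds at all times. Input standardization statistics are computed once
#' from the training set. Fixed seed implies an identical training history.
#'
#' @param net a [build_network()] network.
#' @param X training inputs, n x d_in.
#' @param labels integer class labels in `0..d_out-1`.
#' @param epochs training epochs, default 50.
#' @param batch_size default 128.
#' @param lr adaptive-moment step size, default 1e-3.
#' @param seed shuffling seed.
#' @param X_test,labels_test optional held-out set evaluated each epoch.
#' @return A list: `net` (trained), `history` (data.frame with `epoch`,
#'   `train_accuracy`, `test_accuracy`).
#' @export
train_network <- function(net, X, labels, epochs = 50L, batch_size = 128L,
                          lr = 1e-3, seed = 0L,
                          X_test = NULL, labels_test = NULL) {
  stopifnot(inherits(net, "parallel_net"))
  X <- as.matrix(X)
  labels <- as.integer(labels)
  dout <- net$spec$d_out
  if (any(labels < 0 | labels >= dout)) stop("labels must lie in 0..d_out-1")
  n <- nrow(X)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  net$center <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  net$scale <- ifelse(sds > 0, sds, 1)

  parallel <- net$spec$synapse_mode == "parallel"
  pnames <- c("W1", "b1", "b2", if (parallel) c("A", "S", "T") else "W2")
  mstate <- lapply(pnames, function(p) net[[p]] * 0)
  vstate <- mstate
  names(mstate) <- names(vstate) <- pnames
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  history <- data.frame(epoch = integer(0), train_accuracy = numeric(0),
                        test_accuracy = numeric(0))
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]
      yb <- labels[idx]
      B <- length(idx)
      fw <- forward_full(net, xb)
      Pm <- softmax_rows(fw$scores)
      dS <- Pm
      dS[cbind(seq_len(B), yb + 1L)] <- dS[cbind(seq_len(B), yb + 1L)] - 1
      dS <- dS / B

      grads <- list(b2 = colSums(dS))
      dH <- matrix(0, B, net$spec$d_hidden)
      if (parallel) {
        gA <- net$A * 0; gSp <- net$S * 0; gT <- net$T * 0
        for (o in seq_len(dout)) {
          go <- dS[, o]
          for (m in seq_len(net$spec$M)) {
            a <- net$A[, o, m]; s <- net$S[, o, m]; t <- net$T[, o, m]
            D <- sweep(fw$H, 2, t)
            sig <- 1 / (1 + exp(-sweep(D, 2, s, "*")))
            s1s <- sig * (1 - sig)
            gA[, o, m] <- 2 * a * colSums(go * sig)
            gSp[, o, m] <- a^2 * colSums(go * s1s * D)
            gT[, o, m] <- -a^2 * s * colSums(go * s1s)
            dH <- dH + sweep(go * s1s, 2, a^2 * s, "*")
          }
        }
        grads$A <- gA; grads$S <- gSp; grads$T <- gT
      } else {
        grads$W2 <- crossprod(fw$H, dS)
        dH <- dS %*% t(net$W2)
      }
      dH0 <- dH * (1 / (1 + exp(-fw$H0)))
      grads$W1 <- crossprod(fw$Xn, dH0)
      grads$b1 <- colSums(dH0)

      step <- step + 1L
      for (p in pnames) {
        g <- grads[[p]]
        mstate[[p]] <- beta1 * mstate[[p]] + (1 - beta1) * g
        vstate[[p]] <- beta2 * vstate[[p]] + (1 - beta2) * g^2
        mhat <- mstate[[p]] / (1 - beta1^step)
        vhat <- vstate[[p]] / (1 - beta2^step)
        net[[p]] <- net[[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
      if (parallel) net$S[net$S < 0] <- 0 else net$W2[net$W2 < 0] <- 0
    }
    train_acc <- mean(predict(net, X) == labels)
    test_acc <- if (!is.null(X_test)) {
      mean(predict(net, X_test) == as.integer(labels_test))
    } else {
      NA_real_
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_accuracy = train_acc,
                                         test_accuracy = test_acc))
  }
  list(net = net, history = history)
}

#' Synthetic labeled data for network tests
#'
#' `synth_blobs` draws one Gaussian cluster per class (cluster centers
#' themselves Gaussian, scaled by `sep`); `synth_stripes` renders small
#' digit-like striped bitmaps: each class has a characteristic stripe
#' orientation/period, plus pixel noise. Both are fully deterministic given
#' the seed and stand in for image data in tests.
#'
#' @param n number of samples.
#' @param d_in input dimension (blobs).
#' @param n_classes number of classes.
#' @param sep cluster separation scale (blobs), default 3.
#' @param side bitmap side length (stripes), default 8.
#' @param noise pixel noise sd (stripes), default 0.2.
#' @param seed RNG seed.
#' @return A list with `x` (n x d matrix) and `labels` (integers 0..K-1).
#' @export
synth_blobs <- function(n, d_in = 4L, n_classes = 2L, sep = 3, seed = 0L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  centers <- matrix(stats::rnorm(n_classes * d_in), n_classes, d_in) * sep
  labels <- sample.int(n_classes, n, replace = TRUE) - 1L
  x <- centers[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * d_in), n, d_in)
  list(x = x, labels = labels)
}

#' @rdname synth_blobs
#' @export
synth_stripes <- function(n, side = 8L, n_classes = 4L, noise = 0.2, seed = 0L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  labels <- sample.int(n_classes, n, replace = TRUE) - 1L
  ij <- expand.grid(i = seq_len(side), j = seq_len(side))
  proto <- vapply(seq_len(n_classes) - 1L, function(k) {
    ang <- pi * k / n_classes
    period <- 2 + k %% 3
    as.numeric(((ij$i * cos(ang) + ij$j * sin(ang)) %% period) < period / 2)
  }, numeric(side * side))
  x <- t(proto[, labels + 1L, drop = FALSE]) +
    matrix(stats::rnorm(n * side * side, 0, noise), n, side * side)
  list(x = x, labels = labels)
}

#' Read an MNIST-style IDX file
#'
#' Minimal reader for the standard big-endian IDX format: image files return
#' an n x (rows*cols) matrix scaled to \[0, 1\], label files an integer
#' vector. Only unsigned-byte IDX files (the MNIST distribution format) are
#' supported; all package tests run on [synth_blobs()]/[synth_stripes()], so
#' the real dataset is optional.
#'
#' @param path path to an uncompressed IDX file.
#' @return Matrix (images) or integer vector (labels).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0 || magic[3] != 0x08) {
    stop("not an unsigned-byte IDX file")
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  data <- readBin(con, "integer", n = prod(dims), size = 1, signed = FALSE)
  if (ndim == 1) return(as.integer(data))
  matrix(data / 255, nrow = dims[1], ncol = prod(dims[-1]), byrow = TRUE)
}
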