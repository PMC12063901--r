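#' Aggregate transmission function of one axon
#'
#' The effective input-output curve of an axon is the sum of its parallel
#' synapses' transmission functions (restricted neuron) or its fitted
#' staircase (unrestricted neuron), evaluated on a sorted grid. With
#' `normalize = TRUE` the curve is divided by its maximum, as in the usual
#' normalized-profile plots; an all-flat axon cannot be normalized and is
#' returned unnormalized with `degenerate = TRUE`.
#'
#' @param model a [restricted_neuron] or `staircase_model`.
#' @param axon axon index in `1..N`.
#' @param grid sorted numeric evaluation grid (default 201 equispaced points
#'   over \[0, 1\]).
#' @param normalize divide by the maximum value?
#' @return A list of class `aggregate_function`: `axon`, `grid`, `values`,
#'   `normalized`, `degenerate`.
#' @export
aggregate_function <- function(model, axon, grid = seq(0, 1, length.out = 201),
                               normalize = FALSE) {
  if (is.unsorted(grid)) stop("`grid` must be sorted increasing")
  vals <- if (inherits(model, "restricted_neuron")) {
    if (axon < 1 || axon > nrow(model$amp_root)) stop("axon index out of range")
    v <- numeric(length(grid))
    sig <- if (model$param_form == "sigmoid") {
      function(a, s, t) a^2 * sigmoid(s * (grid - t))
    } else {
      function(a, s, t) 2 * a^2 * sigmoid(2 * s * (grid - t)) - a^2
    }
    for (j in seq_len(ncol(model$amp_root))) {
      v <- v + sig(model$amp_root[axon, j], model$slope[axon, j],
                   model$threshold[axon, j])
    }
    v
  } else if (inherits(model, "staircase_model")) {
    if (axon < 1 || axon > length(model$axons)) stop("axon index out of range")
    axon_transmission(model$axons[[axon]], grid)
  } else {
    stop("`model` must be a restricted_neuron or staircase_model")
  }
  degenerate <- FALSE
  normalized <- FALSE
  if (normalize) {
    mx <- max(abs(vals))
    if (mx > 0) {
      vals <- vals / mx
      normalized <- TRUE
    } else {
      degenerate <- TRUE
    }
  }
  structure(
    list(axon = as.integer(axon), grid = grid, values = vals,
         normalized = normalized, degenerate = degenerate),
    class = "aggregate_function"
  )
}

#' Amplitude-vs-threshold profile of a restricted neuron
#'
#' Bins the thresholds of all N*M synapses into `n_bins` equal-width bins
#' over the input range, and reports per bin the mean amplitude (`a^2`) of
#' the synapses whose threshold falls there (NA for empty bins, which are
#' missing, not zero), plus the threshold and amplitude histograms.
#'
#' A tanh-form neuron is mapped through [to_sigmoid_form()] first so that
#' amplitudes and thresholds are reported in the sigmoid parameterization.
#'
#' @param neuron a [restricted_neuron].
#' @param n_bins number of equal-width bins, default 20.
#' @param input_range length-2 numeric range, default c(0, 1).
#' @return A list: `bin_edges`, `mean_amplitude` (length `n_bins`, NA where
#'   empty), `threshold_counts`, `amplitude_breaks`, `amplitude_counts`.
#' @export
amplitude_threshold_profile <- function(neuron, n_bins = 20L,
                                        input_range = c(0, 1)) {
  stopifnot(inherits(neuron, "restricted_neuron"), n_bins >= 1)
  if (neuron$param_form == "tanh") neuron <- to_sigmoid_form(neuron)
  amp <- as.vector(neuron$amp_root^2)
  thr <- as.vector(neuron$threshold)
  edges <- seq(input_range[1], input_range[2], length.out = n_bins + 1)
  bin <- findInterval(thr, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mean_amp <- rep(NA_real_, n_bins)
  for (b in unique(bin)) mean_amp[b] <- mean(amp[bin == b])
  counts <- tabulate(bin, nbins = n_bins)
  ah <- graphics::hist(amp, plot = FALSE)
  list(bin_edges = edges, mean_amplitude = mean_amp,
       threshold_counts = counts,
       amplitude_breaks = ah$breaks, amplitude_counts = ah$counts)
}

#' Effective synaptic weight profile
#'
#' The effective weight of an axon's synapse set at input `x` is the ratio of
#' its aggregate response to the input, `I(x)/x`; for a linear synapse it is
#' the constant weight, for nonlinear synapses it varies with the input. The
#' ratio is undefined at zero, so the grid must be strictly positive.
#'
#' @inheritParams aggregate_function
#' @param grid strictly positive sorted evaluation grid.
#' @return Numeric vector `aggregate(x)/x` over the grid.
#' @export
effective_weight_profile <- function(model, axon,
                                     grid = seq(0.005, 1, length.out = 200)) {
  if (any(grid <= 0)) stop("`grid` entries must be strictly positive")
  af <- aggregate_function(model, axon, grid, normalize = FALSE)
  af$values / grid
}
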