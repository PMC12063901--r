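#' Serialize trained models to JSON
#'
#' All trained objects (restricted neurons, staircase models, perceptrons,
#' success grids, capacity estimates) round-trip through a plain JSON
#' document carrying a `type` tag, the dimensions, and the flattened
#' parameter arrays at full double precision.
#'
#' @param object a supported model object.
#' @param path output file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reconstructed object.
#' @export
write_model <- function(object, path) {
  doc <- if (inherits(object, "restricted_neuron")) {
    list(type = "restricted_neuron",
         n_axons = nrow(object$amp_root), n_synapses = ncol(object$amp_root),
         param_form = object$param_form,
         amp_root = as.vector(object$amp_root),
         slope = as.vector(object$slope),
         threshold = as.vector(object$threshold),
         soma_threshold = object$soma_threshold)
  } else if (inherits(object, "staircase_model")) {
    list(type = "staircase_model",
         soma_threshold = object$soma_threshold, lambda = object$lambda,
         weights = object$weights, iterations = object$iterations,
         axons = lapply(object$axons, function(a) {
           list(sorted_inputs = a$sorted_inputs, order = a$order,
                values = a$values)
         }))
  } else if (inherits(object, "sign_perceptron")) {
    list(type = "sign_perceptron", weights = object$weights,
         bias_threshold = object$bias_threshold, margin = object$margin)
  } else if (inherits(object, "success_grid")) {
    list(type = "success_grid", model = object$model, N = object$N,
         M = object$M, loads = object$loads, trials = object$trials,
         seeds = as.vector(object$seeds),
         train_seeds = as.vector(object$train_seeds))
  } else if (inherits(object, "capacity_estimate")) {
    c(list(type = "capacity_estimate"), unclass(object))
  } else {
    stop("unsupported object class: ", paste(class(object), collapse = "/"))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(doc$type,
    restricted_neuron = restricted_neuron(
      matrix(doc$amp_root, doc$n_axons, doc$n_synapses),
      matrix(doc$slope, doc$n_axons, doc$n_synapses),
      matrix(doc$threshold, doc$n_axons, doc$n_synapses),
      doc$soma_threshold, doc$param_form
    ),
    staircase_model = staircase_model(
      lapply(seq_len(nrow(doc$axons)), function(i) {
        staircase_axon(doc$axons$sorted_inputs[[i]], doc$axons$order[[i]],
                       doc$axons$values[[i]])
      }),
      doc$soma_threshold, doc$lambda, doc$weights, doc$iterations
    ),
    sign_perceptron = structure(
      list(weights = doc$weights, bias_threshold = doc$bias_threshold,
           margin = doc$margin),
      class = "sign_perceptron"
    ),
    success_grid = structure(
      list(loads = doc$loads, trials = lapply(doc$trials, as.logical),
           seeds = doc$seeds, train_seeds = doc$train_seeds,
           model = doc$model, N = doc$N, M = doc$M),
      class = "success_grid"
    ),
    capacity_estimate = structure(
      doc[setdiff(names(doc), "type")],
      class = "capacity_estimate"
    ),
    stop("unknown model type: ", doc$type)
  )
}
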