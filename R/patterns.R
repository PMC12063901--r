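#' Random binary-classification pattern sets
#'
#' A pattern set is the universal task object of this package: a P x N matrix
#' of axonal input activities (rows are patterns, columns are presynaptic
#' axons) together with a vector of P binary labels in {+1, -1}. Capacity
#' experiments draw both inputs and labels at random: inputs i.i.d. uniform on
#' \[0, 1\] (or standard Gaussian), labels i.i.d. equiprobable +/-1,
#' independent of the inputs.
#'
#' @param inputs numeric matrix, P x N.
#' @param labels numeric vector of +1/-1, length P.
#' @param distribution one of `"uniform01"`, `"gaussian"`, or `"unknown"`
#'   (for sets read from files).
#' @param seed integer seed the set was generated from, or `NA`.
#' @return An object of class `pattern_set`: a list with elements `inputs`,
#'   `labels`, `distribution`, `seed`.
#' @export
pattern_set <- function(inputs, labels, distribution = "unknown", seed = NA_integer_) {
  inputs <- as.matrix(inputs)
  storage.mode(inputs) <- "double"
  labels <- as.numeric(labels)
  if (nrow(inputs) != length(labels)) {
    stop("number of rows of `inputs` must equal length of `labels`")
  }
  if (!all(labels %in% c(-1, 1))) {
    stop("labels must all be +1 or -1")
  }
  distribution <- match.arg(distribution, c("uniform01", "gaussian", "unknown"))
  if (distribution == "uniform01" && (any(inputs < 0) || any(inputs > 1))) {
    stop("uniform01 inputs must lie in [0, 1]")
  }
  structure(
    list(inputs = inputs, labels = labels, distribution = distribution,
         seed = as.integer(seed)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "<pattern_set> P = %d patterns, N = %d axons, distribution = %s, labels: %+d/%+d split %d/%d\n",
    nrow(x$inputs), ncol(x$inputs), x$distribution,
    1L, -1L, sum(x$labels > 0), sum(x$labels < 0)
  ))
  invisible(x)
}

#' Generate a random binary-classification task
#'
#' Inputs x_{i,mu} are drawn i.i.d. from the named distribution, one value per
#' (pattern, axon) pair; labels y_mu are i.i.d. equiprobable +/-1, independent
#' of the inputs (no class balancing). The same (seed, shape, distribution)
#' always yields bit-identical output.
#'
#' @param n_axons N, number of input axons (columns), >= 1.
#' @param n_patterns P, number of patterns (rows), >= 1.
#' @param distribution `"uniform01"` (default) or `"gaussian"` (standard normal).
#' @param seed integer RNG seed.
#' @return A [pattern_set].
#' @examples
#' ps <- generate_patterns(4, 10, seed = 1)
#' range(ps$inputs)
#' @export
generate_patterns <- function(n_axons, n_patterns,
                              distribution = c("uniform01", "gaussian"),
                              seed = 0L) {
  if (length(n_axons) != 1 || is.na(n_axons) || n_axons < 1) {
    stop("`n_axons` must be a positive integer")
  }
  if (length(n_patterns) != 1 || is.na(n_patterns) || n_patterns < 1) {
    stop("`n_patterns` must be a positive integer")
  }
  distribution <- match.arg(distribution)
  n_axons <- as.integer(n_axons)
  n_patterns <- as.integer(n_patterns)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  x <- switch(distribution,
    uniform01 = stats::runif(n_patterns * n_axons),
    gaussian  = stats::rnorm(n_patterns * n_axons)
  )
  inputs <- matrix(x, nrow = n_patterns, ncol = n_axons)
  labels <- ifelse(stats::runif(n_patterns) < 0.5, -1, 1)
  pattern_set(inputs, labels, distribution, seed)
}

#' Read / write pattern sets as delimited text
#'
#' The on-disk dialect is comma-separated values with '.' decimal marks: N
#' input columns followed by one label column of +1/-1 values, with an
#' optional '#'-prefixed header line. `write_patterns` followed by
#' `read_patterns` reproduces the inputs to full stored precision and the
#' labels exactly.
#'
#' @param path file path.
#' @param ps a [pattern_set].
#' @return `read_patterns` returns a [pattern_set] (distribution `"unknown"`);
#'   `write_patterns` returns `path` invisibly.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data rows in ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(fields[[1]])
  if (ncols < 2) stop("pattern file needs at least one input column plus a label column")
  if (any(lengths(fields) != ncols)) {
    stop("ragged rows in pattern file: all rows must have ", ncols, " fields")
  }
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(ncols)))
  if (anyNA(vals)) stop("non-numeric field in pattern file")
  vals <- t(vals)
  labels <- vals[, ncols]
  if (!all(labels %in% c(-1, 1))) {
    stop("label column must contain only +1 and -1")
  }
  pattern_set(vals[, -ncols, drop = FALSE], labels)
}

#' @rdname read_patterns
#' @export
write_patterns <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_set"))
  n <- ncol(ps$inputs)
  header <- paste0("# ", paste(c(sprintf("x%d", seq_len(n)), "label"), collapse = ","))
  rows <- apply(cbind(ps$inputs, ps$labels), 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = ",")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

# Scoped RNG helpers: seed the global RNG for a reproducible draw and restore
# the caller's RNG state afterwards, so library calls do not perturb user code.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive per-task child seeds from one master seed, each < 2^31, reproducible
# in isolation (task k of a batch can be replayed alone).
derive_seeds <- function(seed, n) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}
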