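#' Success-rate grids over the P/N load axis
#'
#' The capacity protocol trains a model on freshly generated random tasks at
#' a grid of loads `P/N` and records, for each load, the Boolean outcomes of
#' `trials_per_load` independent training runs ("success" = all P patterns
#' classified correctly at the end of training). Each task gets its own child
#' seed derived from the master seed, so any single trial can be replayed in
#' isolation and the whole grid is reproducible.
#'
#' @param model `"perceptron"`, `"restricted"` or `"unrestricted"`.
#' @param N number of input axons.
#' @param loads strictly increasing vector of P/N values; `P = round(load*N)`
#'   must be >= 1.
#' @param trials_per_load independent tasks per load (the protocol default
#'   is at least 5).
#' @param seed master seed.
#' @param M parallel synapses per axon (restricted model only).
#' @param distribution input distribution passed to [generate_patterns()].
#' @param config named list of training options forwarded to the trainer:
#'   for `"restricted"` any [train_config()] argument (e.g. `max_epochs`);
#'   for `"unrestricted"` `lambda`, `max_iter`; for `"perceptron"`
#'   `max_epochs`, `margin`, `eta`.
#' @return An object of class `success_grid`: `loads`, `trials` (list of
#'   logical vectors), `seeds`, `model`, `N`, `M`.
#' @export
run_success_grid <- function(model = c("perceptron", "restricted", "unrestricted"),
                             N, loads, trials_per_load = 5L, seed = 0L,
                             M = 2L, distribution = "uniform01",
                             config = list()) {
  model <- match.arg(model)
  stopifnot(N >= 1, trials_per_load >= 1, all(loads > 0))
  if (is.unsorted(loads, strictly = TRUE)) stop("`loads` must be strictly increasing")
  n_loads <- length(loads)
  # independent child seeds for task generation and for training, so the
  # random initialization is not correlated with the pattern draw
  all_seeds <- derive_seeds(seed, 2L * n_loads * trials_per_load)
  task_seeds <- matrix(all_seeds[seq_len(n_loads * trials_per_load)],
                       nrow = trials_per_load)
  train_seeds <- matrix(all_seeds[-seq_len(n_loads * trials_per_load)],
                        nrow = trials_per_load)
  trials <- vector("list", n_loads)
  for (k in seq_len(n_loads)) {
    P <- max(1L, as.integer(round(loads[k] * N)))
    outcomes <- logical(trials_per_load)
    for (r in seq_len(trials_per_load)) {
      ps <- generate_patterns(N, P, distribution, seed = task_seeds[r, k])
      outcomes[r] <- train_once(model, ps, M, train_seeds[r, k], config)
    }
    trials[[k]] <- outcomes
  }
  structure(
    list(loads = loads, trials = trials, seeds = task_seeds,
         train_seeds = train_seeds, model = model,
         N = as.integer(N), M = if (model == "restricted") as.integer(M) else NA_integer_),
    class = "success_grid"
  )
}

train_once <- function(model, ps, M, task_seed, config) {
  pick <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  switch(model,
    perceptron = train_perceptron(
      ps, max_epochs = pick("max_epochs", 5000L),
      margin = pick("margin", 0), eta = pick("eta", 0.01),
      seed = task_seed
    )$success,
    restricted = {
      cfg <- train_config(
        margin = pick("margin", 0.1),
        eta_a = pick("eta_a", NULL), eta_s = pick("eta_s", NULL),
        eta_t = pick("eta_t", NULL), eta_theta = pick("eta_theta", NULL),
        max_epochs = pick("max_epochs", 10000L),
        resurrection_period = pick("resurrection_period", 100L),
        amp_floor = pick("amp_floor", 0.01), seed = task_seed
      )
      train_restricted(ps, M, cfg)$success
    },
    unrestricted = train_unrestricted(
      ps, lambda = pick("lambda", 0.5), max_iter = pick("max_iter", 1000L)
    )$success
  )
}

#' @export
print.success_grid <- function(x, ...) {
  cat(sprintf("<success_grid> model = %s, N = %d%s\n", x$model, x$N,
              if (!is.na(x$M)) sprintf(", M = %d", x$M) else ""))
  print(data.frame(load = x$loads, rate = success_rates(x),
                   trials = lengths(x$trials)))
  invisible(x)
}

#' @rdname run_success_grid
#' @param grid a `success_grid`.
#' @export
success_rates <- function(grid) {
  vapply(grid$trials, mean, numeric(1))
}

#' Fit the 50% crossing of a success-rate grid
#'
#' Interpolates the success rate as a decreasing logistic of the load,
#' `rate(load) = 1 / (1 + exp((load - location)/scale))` with range pinned to
#' \[0, 1\], fit by unweighted least squares over (location, log scale). The
#' estimated capacity `load_star` is the fitted 50% crossing, i.e. the
#' location parameter. Loads are standardized internally before fitting, so
#' the estimate is exactly equivariant under rescaling of the load axis.
#'
#' @param grid a `success_grid`, or a list with `loads` and `trials`.
#' @return An object of class `capacity_estimate`: `load_star`, `ci_std`
#'   (`NA` for a plain fit), `n_resamples`, `fit_params` (location, scale).
#' @export
fit_capacity <- function(grid) {
  rates <- success_rates(grid)
  fit_capacity_rates(grid$loads, rates)
}

fit_capacity_rates <- function(loads, rates) {
  if (!any(rates > 0.5) || !any(rates < 0.5)) {
    stop("cannot bracket the 50% crossing: success rates are ",
         paste(signif(rates, 3), collapse = ", "),
         " (need at least one rate above and one below 0.5)")
  }
  mid <- mean(range(loads)); span <- diff(range(loads))
  if (span == 0) stop("need at least two distinct loads")
  u <- (loads - mid) / span
  obj <- function(par) {
    f <- 1 / (1 + exp((u - par[1]) / exp(par[2])))
    sum((rates - f)^2)
  }
  fit <- stats::optim(c(0, log(0.25)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000))
  }
  location <- mid + span * fit$par[1]
  scale <- span * exp(fit$par[2])
  structure(
    list(load_star = location, ci_std = NA_real_, n_resamples = 0L,
         fit_params = c(location = location, scale = scale)),
    class = "capacity_estimate"
  )
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf("<capacity_estimate> P*/N = %.4g%s\n", x$load_star,
              if (is.finite(x$ci_std)) sprintf(" +/- %.3g (sd over %d resamples)",
                                               x$ci_std, x$n_resamples) else ""))
  invisible(x)
}

#' Resampling confidence interval for the capacity
#'
#' Repeats `n_resamples` times: at every load draw half of that load's trials
#' without replacement, refit the logistic, and record the 50% crossing.
#' Returns the mean of the resampled estimates as `load_star` and their
#' standard deviation as `ci_std` (the error bar of the capacity plots).
#' Resamples whose half-grid no longer brackets the crossing are recorded as
#' `NA` and excluded from the summary.
#'
#' @param grid a `success_grid`; every load needs at least 2 trials.
#' @param n_resamples default 100.
#' @param seed RNG seed for the resampling.
#' @return A `capacity_estimate` with the vector of resampled crossings in
#'   `$resamples`.
#' @export
bootstrap_capacity <- function(grid, n_resamples = 100L, seed = 0L) {
  stopifnot(n_resamples >= 1)
  if (any(lengths(grid$trials) < 2)) {
    stop("every load needs at least 2 trials to resample")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  draws <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    rates <- vapply(grid$trials, function(tr) {
      half <- max(1L, length(tr) %/% 2L)
      mean(tr[sample.int(length(tr), half)])
    }, numeric(1))
    draws[b] <- tryCatch(
      fit_capacity_rates(grid$loads, rates)$load_star,
      error = function(e) NA_real_
    )
  }
  ok <- draws[is.finite(draws)]
  if (length(ok) == 0) stop("no resample bracketed the 50% crossing")
  full <- tryCatch(fit_capacity(grid)$fit_params, error = function(e) c(NA, NA))
  structure(
    list(load_star = mean(ok),
         ci_std = if (length(ok) > 1) stats::sd(ok) else 0,
         n_resamples = as.integer(n_resamples),
         fit_params = full, resamples = draws),
    class = "capacity_estimate"
  )
}

#' Bracket the capacity by doubling/halving the load
#'
#' Pilot search for a sensible load grid: starting from `load = 1`, the load
#' is doubled while quick trials still mostly succeed and halved while they
#' mostly fail, until the 50% crossing is bracketed; a geometric grid spanning
#' the bracket is returned.
#'
#' @inheritParams run_success_grid
#' @param pilot_trials quick trials per probe, default 3.
#' @param n_loads grid size returned, default 5.
#' @return Increasing numeric vector of loads.
#' @export
auto_loads <- function(model, N, pilot_trials = 3L, n_loads = 5L, seed = 0L,
                       M = 2L, distribution = "uniform01", config = list()) {
  probe <- function(load) {
    g <- run_success_grid(model, N, load, pilot_trials, seed = seed + round(1000 * load),
                          M = M, distribution = distribution, config = config)
    success_rates(g)
  }
  lo <- hi <- 1
  r <- probe(1)
  if (r > 0.5) {
    while (r > 0.5 && hi < 1024) { hi <- hi * 2; r <- probe(hi) }
    lo <- hi / 2
  } else {
    while (r <= 0.5 && lo > 1 / N) { lo <- lo / 2; r <- probe(lo) }
    hi <- lo * 2
  }
  exp(seq(log(lo * 0.7), log(hi * 1.4), length.out = n_loads))
}
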