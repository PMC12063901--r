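# parsyn: parallel-synapse neuron models and classification capacity

Cortical neurons often receive several synaptic contacts from the *same*
presynaptic axon. If each of those parallel synapses can learn its own
nonlinear, monotone transmission function, the neuron stops being a plain
perceptron: the sum of differently-tuned sigmoids on each axon is a flexible
monotone input-output curve, and the neuron's ability to memorize random
input/label assignments grows well beyond the classical limit. `parsyn`
implements the models and the measurement protocol for this question, for
computational neuroscientists who want to reproduce, extend, or stress-test
single-neuron capacity results.

## Models

* **Restricted neuron** — `N` axons × `M` synapses; synapse `(i, j)`
  contributes `a²ᵢⱼ · σ(sᵢⱼ(xᵢ − tᵢⱼ))` with `s ≥ 0`; prediction
  `ŷ = sign(Σᵢⱼ hᵢⱼ(xᵢ) − θ)`. Trained by full-batch gradient descent on the
  hinge loss `L = Σ_μ max(0, ε − (z_μ − θ)y_μ)` (ε = 0.1) over the
  margin-violating set, with periodic "resurrection" of dead synapses.
  A compiled (Rcpp) loop and an R reference loop produce identical
  trajectories.
* **Unrestricted neuron** — each axon carries an arbitrary nonnegative
  nondecreasing staircase `I` fitted by exact weighted isotonic regression
  (greatest-convex-minorant envelope of the cumulative `y·w` walk) under the
  objective `−Σ w_μ y_μ I_μ + λ Σ I_μ²`, inside an importance-reweighting
  loop (`w_μ ← w_μ + 1` on every miss).
* **Sign-constrained perceptron** — nonnegative-weight online margin
  perceptron; the capacity baseline `P*/N → 1`.
* **Capacity protocol** — success grids over `P/N`, logistic interpolation of
  the 50% crossing, half-sample bootstrap error bars.
* **Network extension** — a two-layer classifier whose hidden→output
  connections are parallel sigmoidal synapses (`(D_in+1)D_hidden +
  (3M·D_hidden+1)D_out` parameters), plus the parameter-matched
  nonnegative-linear comparison net.

## Worked example

```r
library(parsyn)

## a random task: 25 axons, 50 patterns (load P/N = 2)
ps  <- generate_patterns(n_axons = 25, n_patterns = 50, seed = 1)
fit <- train_restricted(ps, M = 2, train_config(max_epochs = 2e5, seed = 1))
fit$success
#> [1] TRUE
fit$epochs_used
#> [1] 1051
mean(predict(fit$neuron, ps) == ps$labels)
#> [1] 1

## the same task is trivial for the unrestricted (staircase) neuron
train_unrestricted(ps, lambda = 0.5)$iterations_used
#> [1] 23

## measuring a small capacity curve for the perceptron baseline
grid <- run_success_grid("perceptron", N = 100,
                         loads = c(0.6, 0.8, 0.9, 1.0, 1.2),
                         trials_per_load = 10, seed = 7,
                         config = list(max_epochs = 2e4))
success_rates(grid)
#> [1] 1.0 1.0 0.3 0.5 0.1
bootstrap_capacity(grid, n_resamples = 100, seed = 8)
#> <capacity_estimate> P*/N = 0.9393 +/- 0.0484 (sd over 100 resamples)
```

The last number is the estimated classification capacity `P*/N` of the
sign-constrained perceptron at `N = 100`: the load at which the fitted
success-rate curve crosses 50%, with the standard deviation of 100
half-sample refits as its error bar — consistent with the asymptotic value
of 1 approached from below at finite `N`. The restricted neuron at `M = 2`
crosses 50% near `P/N ≈ 3` at `N = 25` (and higher at larger `N`), which is
the headline effect: two learnable sigmoids per axon already outperform the
linear baseline several-fold.

The envelope solver is exposed directly:

```r
envelope_solve(labels = c(-1, 1, 1), weights = c(1, 2, 1), lambda = 0.5)
#> [1] 0.0 1.5 1.5
```

## Command line

```sh
Rscript -e 'parsyn::parsyn_cli()' generate --n-axons 20 --n-patterns 30 --seed 1 --out task.csv
Rscript -e 'parsyn::parsyn_cli()' train-restricted --in task.csv --m 2 --out model.json
Rscript -e 'parsyn::parsyn_cli()' analyze --model model.json --axon 1 --out axon1.csv
Rscript -e 'parsyn::parsyn_cli()' capacity --model perceptron --n 100 --loads 0.6,0.8,1.0,1.2 --trials 10
```

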