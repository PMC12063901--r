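---
title: "Parallel-synapse neuron models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel-synapse neuron models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsyn)
```

## The scientific question

Cortical neurons frequently receive several synaptic contacts from the same
presynaptic axon. If those parallel synapses all transmitted the same linear
function of the presynaptic activity, they would be redundant: their sum
would still be linear, and the neuron would compute exactly what a
single-synapse neuron computes. This package implements single-neuron models
in which each parallel synapse transmits a *nonlinear, monotone* function of
its input, and asks how much the classification capacity of the neuron
grows as a consequence.

Capacity is measured operationally: draw `P` random patterns over `N` input
axons (entries i.i.d. uniform on [0, 1], or standard Gaussian) with i.i.d.
equiprobable ±1 labels, train the neuron, and call the run a success only if
*all* `P` patterns end up correctly classified. The capacity `P*/N` is the
load at which the success probability crosses 50%.

## Models

**Restricted neuron.** Each of the `N` axons makes `M` synapses; synapse
`(i, j)` contributes `a[i,j]^2 * sigmoid(s[i,j] * (x[i] - t[i,j]))` to the
somatic current. The amplitude is stored as a square so it can never become
negative, and the slope `s` is constrained nonnegative, so every synapse is
excitatory and monotone (a soft version of Dale's law). The somatic current
is the plain sum over all `N*M` synapses — no dendritic nonlinearities — and
the prediction is `sign(z - theta)`. Training minimizes the summed hinge
loss with margin 0.1 by full-batch gradient descent on all four parameter
groups, evaluated over the set of margin-violating patterns.

During training we use the algebraically equivalent tanh parameterization
`a'^2 * tanh(s'(x - t'))`, which is centered at zero and makes the somatic
threshold easier to learn; `to_sigmoid_form()` maps back for reporting.
One wrinkle: the widely quoted parameter mapping for this change of form
carries a sign error in its threshold offset. The identity
`tanh(u) = 2*sigmoid(2u) - 1` forces `z_tanh = z_sigmoid - sum(a'^2)` and
hence `theta_sigmoid = theta_tanh + sum(a'^2)`; the package uses this
offset, and the form-equivalence test verifies `z - theta` is preserved to
1e-10 — with the opposite sign it is off by `2*sum(a'^2)`.

**Unrestricted neuron.** In the limit of unlimited synapses per axon, the
per-axon aggregate transmission becomes an arbitrary monotone nondecreasing
function. On `P` data points it takes at most `P` values, so it is
parameterized as a staircase over the axon's sorted inputs, with the first
value pinned at 0 (the somatic threshold absorbs the offset) and tied
inputs sharing one value. For fixed per-pattern importance weights `w`, the
per-axon problem

    minimize  -sum(w * y * I) + lambda * sum(I^2)   over  0 = I[1] <= I[2] <= ...

is a weighted isotonic regression in disguise (complete the square: the
targets are `y*w/(2*lambda)`), solved exactly by one pool-adjacent-violators
pass — equivalently, by reading the positive segment slopes off the greatest
convex minorant of the cumulative walk of `y*w`. The classifier is built
iteratively: solve all axons, set the somatic threshold, increment the
weight of every misclassified pattern by one, repeat. Hard patterns thus
pull harder on the next round, a boosting-like reweighting.

**Baseline.** A sign-constrained perceptron (single linear nonnegative
weight per axon, step nonlinearity), whose asymptotic capacity on random
patterns is `P*/N = 1`. It is trained with the classical online
margin-perceptron rule with projection onto the nonnegative orthant after
every update.

## The capacity protocol

`run_success_grid()` trains freshly generated tasks at a grid of loads
(at least 5 trials per load; every task has its own derived seed so any
trial can be replayed in isolation). `fit_capacity()` interpolates the
success rate with a two-parameter decreasing logistic pinned to [0, 1] by
least squares; the 50% crossing is the capacity estimate. Loads are
standardized internally before fitting, which makes the estimate exactly
equivariant under rescaling of the load axis. `bootstrap_capacity()` redraws
half of each load's trials without replacement, refits 100 times, and
reports the standard deviation of the crossings as the error bar.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `margin` | 0.1 | hinge margin; patterns correct by less than this still drive updates |
| `eta_a, eta_s, eta_t, eta_theta` | `c(0.05, 0.5, 0.15, 0.05)/P` | learning rates (see below) |
| `max_epochs` | 10000 | epoch budget; capacity runs near the critical load need ~2e5 |
| `resurrection_period` | 100 | epochs between sweeps restoring dead synapses |
| `amp_floor` | 0.01 | amplitude restored to resurrected synapses |
| `lambda` | 0.5 | L2 penalty of the envelope objective; the solution scales exactly as 1/lambda |
| `max_iter` | 1000 | reweighting iterations for the unrestricted trainer |

**Why 1/P-scaled, per-parameter learning rates.** The update rule sums
gradients over the violating set, so with constant rates the effective step
grows linearly with `P`. The amplitude update is multiplicative (relative
change about `2*eta*|Omega|` per epoch); with a flat rate of 0.01 and a few
dozen violators the amplitudes oscillate indefinitely and training never
converges beyond `P/N ~ 1` (measured: success rate 0 at `P/N = 2`, `N = 25`,
20k epochs). Scaling all rates by `1/P` restores stability. Slopes get a
10x faster rate and thresholds 3x, because their gradients carry an extra
factor of the squared amplitude — typically ~0.01–0.1 — and would otherwise
barely move over any realistic budget. With these defaults the model reaches
success rate 1.0 at `P/N = 2` and ~0.5 at `P/N = 3` (`N = 25`, `M = 2`,
3e5 epochs). The exact rates used in the original experiments are not
public; all four remain configurable.

**Synapse resurrection.** Synapses whose amplitude collapses have vanishing
gradients in *all* their parameters and are permanently stuck. Every
`resurrection_period` epochs, any synapse with amplitude below `amp_floor`
is restored to exactly the floor and its threshold is redrawn from a
Beta(1/2, 1/2) law rescaled to the input range — U-shaped, mimicking the
edge-biased threshold distribution that training itself discovers (most
discriminative structure in a uniform input ensemble sits near the edges of
the support).

## Numerical choices and tie-breaks

* `sign(0)` is deterministically −1, both for predictions and success
  checks: a pattern sitting exactly on the threshold counts as class −1.
* Training drives updates from the ε-margin violators, but *success* is
  strict correctness `(z - theta)*y > 0` for all patterns.
* Slope nonnegativity is enforced by clipping at 0 after each update.
* The unrestricted model's somatic threshold is not part of the original
  formulation; the package sets it after each iteration by a deterministic
  scan over midpoints of the sorted somatic sums, minimizing the number of
  misclassifications with ties broken toward the smaller threshold. This is
  optimal for the 1-D subproblem and consistent with pinning `I[1] = 0`.
* Staircases are right-continuous: the value at a breakpoint is the value
  fitted at that input, so training inputs reproduce their fitted currents
  exactly.
* Non-finite parameters (a diverged run with user-supplied rates) can never
  be reported as success: the success check requires strictly positive
  margins and fails on NaN.
* `fit_capacity()` requires rates on both sides of 50% and errors otherwise;
  bootstrap resamples that lose the bracket are dropped (recorded as `NA`).
* Success grids derive *separate* child seeds for the pattern draw and for
  the training initialization of each trial. Reusing one seed makes the
  initial thresholds and amplitudes literal copies of the first input
  values (both are the first uniforms of the same stream), and this hidden
  correlation measurably depresses training success.

## The network extension

`build_network()`/`train_network()` embed a parallel-synapse layer between
the hidden and output layers of a two-layer classifier: each of the
`d_hidden * d_out` connections carries `M` sigmoidal synapses with the same
parameterization as the restricted neuron, giving
`(d_in + 1) d_hidden + (3 M d_hidden + 1) d_out` learnable values. The
comparison network replaces them with single linear synapses clipped to
nonnegative weights (`(d_in + 1) d_hidden + (d_hidden + 1) d_out`
parameters); matching total counts is done by widening its hidden layer.
Hidden units are Softplus; training is mini-batch adaptive-moment descent
on the softmax cross-entropy, with the monotonicity constraints re-projected
after every step. Inputs are standardized with training-set statistics
computed once at the start of training (a deliberate simplification of
per-batch normalization: it keeps the forward map deterministic and the
manual gradients simple; on the small dense inputs used here the two are
nearly indistinguishable). Raw scores feed the loss — the smooth rectifier
is hidden-layer only.

## What the synthetic data does and does not establish

`generate_patterns()` emulates exactly the stated benchmark: i.i.d.
uniform (or Gaussian) inputs with independent equiprobable labels. Real
neural inputs are correlated and structured; a capacity measured here is a
property of the random-pattern ensemble, not of any natural task. The
network tests use `synth_blobs()` (Gaussian clusters — linearly separable,
so any sane classifier reaches ~100% training accuracy; a green test
establishes the plumbing and the constraints, not generalization) and
`synth_stripes()` (noisy oriented-stripe bitmaps — a harder multi-class
surrogate for digit images). Real MNIST IDX files can be read with
`read_idx()` but no test depends on them.

## Known limitations

* Full-scale capacity curves (N up to 1000, with P into the tens of
  thousands) are supported by the code but take cluster-scale compute; the
  test suite runs reduced pilots (N = 25–200) and the measured capacities at
  small N sit below the large-N figures, as expected from the increasing
  capacity-vs-N trend.
* The gradient trainer's success near the critical load depends on the
  epoch budget; reported capacities are algorithmic (model + optimizer +
  budget), not information-theoretic limits.
* Online (one-pattern-at-a-time) learning and noise-corrupted or pruned
  variants are out of scope.
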