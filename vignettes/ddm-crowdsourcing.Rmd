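---
title: "Crowdsourced label aggregation with drift-diffusion annotator models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowdsourced label aggregation with drift-diffusion annotator models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmcrowd)
```

## The model

`ddmcrowd` aggregates binary labels from annotators of unknown reliability.
Instead of putting a beta or Dirichlet prior directly on each annotator's
confusion matrix, it assumes that every labeling decision is produced by a
drift-diffusion process: conditional on the (hidden) truth $z_i$ of item
$i$, annotator $j$ accumulates evidence

$$X(t + dt) = X(t) + \mu\, dt + \sigma\, Y(t), \qquad Y(t) \sim N(0, dt),$$

started at $X(0) = 0$, until $|X(t)| \ge 1$. Absorption at $+1$ produces
the correct label, absorption at $-1$ the incorrect one, and the
first-passage time is the reaction time. Each annotator has two parameter
pairs, $(\mu_0^j, \sigma_0^j)$ used when $z = 0$ and
$(\mu_1^j, \sigma_1^j)$ used when $z = 1$, so reliability can differ by
condition.

Two closed forms make this tractable. Writing $S$ for the logistic
function, the probability of hitting $+1$ first is

$$P(\text{correct}) = S\!\left(\frac{2\mu}{\sigma^2}\right),$$

so annotator specificity is $S(2\mu_0/\sigma_0^2)$ and sensitivity
$S(2\mu_1/\sigma_1^2)$; and the optional stopping theorem
$E[X(\tau)] = \mu E[\tau]$ gives the expected decision time
$E[\tau] = (2P(\text{correct}) - 1)/\mu$, with the driftless limit
$1/\sigma^2$. Both are implemented in `correct_probability()` and
`expected_decision_time()`.

A key structural fact follows: labels alone identify an annotator only
through $\mu/\sigma^2$. The map
$(\mu, \sigma) \to (c\mu, \sqrt{c}\,\sigma)$ leaves every response
probability unchanged while scaling expected decision times by $1/c$.
Reaction times therefore carry exactly the information that resolves the
scale of the parameters — this is why the two reaction-time-aware fitting
methods exist.

Item truths are tied to features through a zero-mean Gaussian-process
latent $f$ with the logistic link: the per-item weight carried by the
latent is $S(f_i)$. Under the package's default convention the weight and
the posterior $q_i$ refer to condition $z = 0$ (the pairing used in the
likelihood), and every user-facing function takes a `positive_branch` flag
that flips the convention globally and consistently.

## The variational objective

With a mean-field factorization over item labels, latents and annotator
parameters, and with the latent and annotator factors collapsed to point
values (the objective below contains them directly, not in expectation),
the evidence lower bound is

$$g = \sum_i \ln\Big[S(f_i) \prod_j P(y_{ij}\mid z{=}0)
      + (1 - S(f_i)) \prod_j P(y_{ij}\mid z{=}1)\Big]
      + \sum_i \big[q_i \ln S(f_i) + (1-q_i)\ln(1 - S(f_i))\big]
      - \sum_i \big[q_i \ln q_i + (1-q_i)\ln(1-q_i)\big],$$

where $P(y\mid z{=}0)$ is $S(2\mu_0/\sigma_0^2)$ for $y = 0$ and its
complement for $y = 1$, and analogously for condition 1. The entropy term
makes the objective strictly concave in each $q_i$, with the
coordinate-wise optimum $q_i = S(f_i)$.

Two forms of the likelihood term are provided.
`likelihood_form = "product"` (the default, shown above) is the mixture
implied by the model's own conditional-independence assumption: annotators
are independent given the truth, so their response probabilities multiply
within each branch. `likelihood_form = "printed"` instead places a sum
over annotators inside the logarithm. The printed form is kept because it
appears in derivations of this objective, but it is not a likelihood of
independent annotators: its per-item score is linear in each annotator's
response probability, so at its optimum the items are classified by a
linear (Youden-index-weighted) vote. On the synthetic benchmark below that
caps crowdsourced accuracy around 95% fully converged (and much lower
under the default iteration budget), whereas the product form reaches the
~98% that optimal label-only aggregation allows. The product form is
therefore the default and the one used by the acceptance checks.

### Constraints and optimization

All (0,1)-bounded blocks ($q$ and the four annotator parameter vectors)
are softly constrained by adding, per block,

$$c(v) = -e^{\beta(\max(v) - 1)} - e^{-\beta \min(v)}, \qquad \beta = 30,$$

which is negligible strictly inside the unit interval and overwhelms the
likelihood as an extreme entry approaches 0 or 1. The latent block $f$ is
left unconstrained by default (`constrain_f = FALSE`): $f$ must span both
signs to encode both labels, so constraining it to (0,1) would collapse
every item onto one class. The base of the first term is configurable;
the default is $e$, matching the second term.

Optimization is full-batch gradient ascent with learning rate 0.01, all
parameters initialized at 0.5, stopping at the *later* of 300 iterations
and an absolute ELBO change below 0.1, with a hard cap of 5000 iterations.
Gradients are analytic (they are verified against central finite
differences at relative $10^{-4}$ in the test suite). One numerical
safeguard is applied: each gradient block is clipped component-wise at
`grad_clip = 1` before the update, so no coordinate moves by more than
0.01 per iteration. The mixture log-likelihood is cliff-shaped near
saturated response probabilities — the all-0.5 initialization implies
$S(4) \approx 0.98$ annotator accuracy, so early responsibility-weighted
gradients on $\sigma$ reach magnitudes of ~50-70 and a fixed-rate update
would step $\sigma$ out of its domain. Clipping bounds the step while
leaving the reported gradient values exact.

Degenerate inputs are legal: all-zero or all-one label columns are kept
interior by the penalty; $q$ is clipped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-9}$ inside logarithms; exact ties $q_i = 0.5$
deterministically resolve to class 0.

### Reaction-time integration

`fit_variational()` offers three variants:

* **`method = "plain"`** — labels only; the parameter scale along each
  accuracy ridge remains unidentified.
* **`method = "1"`** — adds the regularizer
  $-\lambda \sum_{j,c} \big(E[\tau](\mu_c^j, \sigma_c^j) -
  \overline{rt}_{jc}\big)^2$ to the objective, where
  $\overline{rt}_{jc}$ is the observed mean reaction time of annotator
  $j$ on the items currently assigned to condition $c$ (thresholding $q$
  at 0.5). The means are refreshed every iteration and treated as
  constants in the gradient, so the regularizer acts like an
  expectation-style target on the Wald identity. $\lambda$ defaults to 1
  (the squared-seconds deviations are on the same order as the per-item
  log-likelihood contributions); it is a config knob.
* **`method = "2"`** — plain ascent followed by `rescale_by_rt()`: for
  each annotator and condition the accuracy-preserving map above is
  applied with $c = E[\tau](\hat\mu, \hat\sigma)/\overline{rt}_{jc}$,
  which matches the model-implied expected decision time to the observed
  mean exactly while leaving sensitivities and specificities untouched to
  machine precision. Conditions with no assigned items are left as they
  are.

The functional forms of both reaction-time mechanisms are this package's
own reconstruction from the Wald identity; only their roles (an in-
objective regularizer versus a post-hoc rescaling) are fixed by the
reference procedure.

Prior-support estimates (`estimate_supports()`) are the per-parameter
minima and maxima of the recovered annotator pool, normalized per symbol
family (lower bound = minimum, upper bound = maximum, for each of
$\mu_0, \mu_1, \sigma_0, \sigma_1$).

## The synthetic world

The generator reproduces the benchmark conditions end to end:

* 200 items uniform on $[0, 2\pi] \times [-1, 1]$, labeled $z = 0$ iff
  $\sin(x_1) < x_2$ — a nonlinear, sinusoidal decision boundary splitting
  the rectangle into equal-area classes;
* 10 annotators with condition-specific parameters drawn uniformly from
  preset supports (`experiment_preset("exp1")`: drift U(0.1, 0.5) and
  diffusion U(0.5, 0.9) in both conditions; `"exp2"`: condition-0 drift
  U(0.1, 0.4) and diffusion U(0.5, 0.7), condition-1 drift U(0.2, 0.5)
  and diffusion U(0.5, 0.9));
* labels and reaction times from literal Euler-Maruyama paths at
  `dt = 0.01`, terminated at the first step with $|X| \ge 1$, the label
  decided by the sign at the absorbing step (overshoot uncorrected) and
  the reaction time a positive multiple of `dt`.

Each annotator consumes a dedicated random substream derived from the
root seed, so enlarging a pool never perturbs existing label columns, and
every pipeline stage (items, pool, labels, test grid, optimizer restarts)
draws from its own derived seed. Reruns are byte-identical.

What the generator does *not* emulate matters for interpreting green
tests: real annotators whose reaction times include delays unrelated to
the decision process (lapses, interface latency), time-varying drift,
annotator learning or collaboration, and feature-dependent difficulty
within a class are all outside the generative family. Passing tests show
that the inference machinery recovers the parameters of data that truly
follow the model, not that human crowds do.

### Discretization facts

Discrete crossing detection biases first-passage functionals upward by
$O(\sqrt{dt})$ (boundary overshoot plus missed within-step crossings).
At `dt = 0.001` the bias on mean decision times is ~2-3% — several Monte-
Carlo standard errors at $10^5$ paths — while hit probabilities are
affected much less. The package therefore keeps the literal scheme for
data generation (the benchmark's definition) but, when a simulation is
used as an *oracle for the continuous-time closed forms*, the tests
shrink the absorbing boundary by the standard continuity correction
$0.5826\,\sigma\sqrt{dt}$, which removes the leading-order term; with it,
all 18 grid statistics agree with the closed forms within 3 SE at $10^5$
paths. A separate consistency check verifies that halving `dt` moves the
empirical correct fraction by less than the Monte-Carlo noise.

## The Gaussian-process classifier

After inference, a zero-mean GP regressor maps item features to the
inferred latent values: RBF kernel (amplitude $\delta^2$, length scale
$\ell$) plus a white-noise kernel, hyperparameters chosen by maximizing
the Cholesky-form log marginal likelihood with L-BFGS-B in log space.
Bounds follow the reference setup: length scale in $[0.001, 1000]$ and
white-noise *variance* in $[0.001, 10]$ (the reference text does not say
whether its white-kernel bound applies to the variance or the amplitude;
variance is this package's reading). The amplitude bound $[0.001, 1000]$
is the package's own choice, wide enough to be inactive in practice. Five
optimizer starts are used — one default start at
$(\delta^2, \ell, \sigma_n^2) = (1, 1, 0.1)$ plus four seeded log-uniform
draws — because the marginal likelihood is multimodal in the length
scale; the reference setup is silent on restarts.

A new point $x^*$ receives the posterior-mean latent $f^*$; under the
default inference convention ($S(f) = P(z{=}0)$) the label is $z^* = 1$
iff $f^* < 0$, with the exact tie $f^* = 0$ resolved to class 0 for
determinism, and $p^*$ is always reported on the $P(z{=}1)$ scale.
The majority-vote baseline trains the same GP on $\pm 1$-encoded majority
labels (ties to class 0).

## Problem sizes, benchmarks and known limitations

The replicated benchmark used by the package's own acceptance checks and
by `scripts/acceptance.R` runs both presets with methods 1 and 2 over 10
replicate seeds each (40 pipeline runs: simulate, infer, train the GP,
classify a fresh 10,000-point uniform grid sample that is shared across
methods within a seed). Typical results: drift and diffusion MSEs of
order $10^{-3}$ (two orders of magnitude below the reference bounds of
0.0841 and 0.134 — the reaction-time constraints pin the scale that
labels cannot), crowdsourced-label accuracy ~98%, GP accuracy ~95%.

Two honest gaps against the reference figures are worth recording:

* The reference crowdsourced rates (99.0/99.1/98.9 in experiment 1) come
  from a *single* annotator draw. The Bayes-optimal label-only
  aggregator, given the true annotator parameters, averages 98.0%
  accuracy over draws from the experiment-1 priors; a multi-seed mean
  therefore cannot sit at 99% for every rate, and per-seed rate floors of
  97.9% hold only in a minority of seeds. The corresponding acceptance
  check is kept at its stated threshold and allowed to fail rather than
  weakened.
* GP sensitivity runs ~5 points below GP specificity under the default
  convention: the latent block starts at $+0.5$ (the "all parameters at
  0.5" initialization), so class-1 items must cross zero and the class-1
  side of the latent field is systematically weaker after a finite
  iteration budget. The global convention flip mirrors the asymmetry, as
  the symmetry tests verify.

Other limitations: non-binary labels, time-varying drift/diffusion, and
annotator interaction models are out of scope; the optimizer is
full-batch (no minibatching), and annotator parameters are point
estimates, not posteriors.

## Reading the outputs

`fit_variational()` returns posterior probabilities `q` (of the
`positive_branch` condition), latents `f`, the annotator table with
analytic sensitivity/specificity, and the per-iteration objective trace.
`run_experiment()` wraps the full pipeline and recomputes every reported
metric from raw predictions; `run_replicates()` aggregates means and SDs
across seeds. Datasets travel as `items.csv` + `labels.csv` (+
`annotators.csv` when the generating parameters are known) with floats at
17 significant digits for exact round-trips; results and reports are
versioned JSON. The `inst/cli/ddmcrowd` script exposes `simulate`,
`infer`, `evaluate`, `run-experiment` and `predict` over the same
functions.
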