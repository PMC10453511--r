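---
title: "Simulating gene expression with per-gene forecasters and inferring regulatory networks by in-silico perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene expression with per-gene forecasters and inferring regulatory networks by in-silico perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesgrn)
```

## The model

`aesgrn` treats a gene-expression system of $n$ genes as a collection of
interacting forecasting *agents*. Agent $A_i$ is a learned function
$h_i : \mathbb{R}^{n \times m} \to \mathbb{R}$ that predicts gene $i$'s next
expression value from the *state matrix* $X(t)$, the last $m$ normalized
expression values of **all** genes:

$$x_i(t+1) = h_i(X(t)), \qquad
  x(t+1) = \big(h_1(X(t)), \dots, h_n(X(t))\big).$$

The agents share one state matrix and are advanced by a synchronous clock:
every agent reads the same pre-step state, the new state vector is appended,
and the oldest column is dropped. This closed loop — the artificial
environmental setting (AES) — is a simulator of the expression system; once
it reproduces the observed trajectories well, it can be interrogated *in
silico*: force one gene's row of the state matrix to follow a perturbation
function, watch the other genes respond, and read regulatory structure off
the responses.

Three assumptions are baked in. First, a first-order Markov window: all
information relevant to the next value is contained in the last $m$
observations. Second, synchronous discrete-time updates; the data's sampling
interval is the simulation step. Third, one freely parameterized forecaster
per gene — nothing constrains $h_i$ to any mechanistic form, so the learned
coupling is phenomenological, not kinetic.

## From dataset to supervised sets

Input data are time-series experiments: $k$ blocks of $b$ observations over
the same $n$ genes (`read_expression`, blank-line-separated TSV blocks or
multiple files). Each gene is min–max normalized to $[0,1]$ with constants
computed on the *training* experiments only (by default the first 60% of
experiments); evaluation experiments are transformed with the same constants
and may fall slightly outside the unit interval. A gene constant over the
training experiments carries no trainable signal and is mapped to zero, with
a warning.

Each agent trains on its own sliding-window regression set: every window of
$m$ consecutive observations, flattened **gene-major** (gene 1's $m$ lags
oldest-first, then gene 2's, ...), paired with the agent gene's value one
step after the window. An experiment of $b$ rows contributes exactly $b-m$
samples; windows never straddle experiment boundaries. The flattening order
is fixed and documented because trained networks are not permutation
invariant.

## Agent architectures and training

Three fixed skeletons are supported (`agent_spec`): a three-block
fully-connected network (FCNN); a 1-D convolutional network (64 filters,
kernel 2 along the time axis with genes as channels, max-pool 2, two dense
blocks); and a recurrent network (LSTM over the $m$ steps, last hidden
state, two dense blocks). The convolution is preceded by a one-step zero-pad
on the oldest side so the feature sequence keeps length $m$ and pools to
$\lfloor m/2 \rfloor$. All networks end in a scalar linear output.

Training minimizes mean-squared error with full-batch Adam on a
chronological 80/20 train/test split, early-stopping on the held-out error
(patience 20, at most 300 epochs, learning rate $10^{-2}$) and keeping the
best-scoring weights. Full-batch gradients are exact at these sample sizes
(tens of rows), make runs bit-reproducible given a seed, and avoid
mini-batch RNG bookkeeping; the fairly high default learning rate is what
full-batch Adam needs to converge within a few hundred epochs on unit-scale
targets. The engine (dense/conv/LSTM forward and backward passes) is
implemented in plain R and verified against finite-difference gradients in
the test suite.

Hyperparameters can be tuned by seeded random search
(`tune_hyperparameters`) over a declared space: dense widths
$\{16,32,64,128\}$, activations $\{$relu, tanh, sigmoid$\}$, dropout
$U[0, 0.5]$, LSTM units $\{16,32,64\}$, learning rate log-uniform
$[10^{-4}, 10^{-2}]$. The winner is the spec with the lowest held-out error;
ties go to the first evaluated.

## Judging the simulator

A fitted AES is seeded with the first $m$ observations of the evaluation
target — the element-wise mean over *all* $k$ experiments, training and
held-out alike — and run freely for the target's full length. The first $m$
columns are shared initial conditions, so all metrics use only the $b-m$
genuinely predicted columns. Per gene we compute Pearson correlation, cosine
similarity, MSE and MAE against the target and average them arithmetically
into the aggregate reliabilities ($R_\rho$, $R_\eta$, reported as
percentages) and errors ($\mathrm{Err}_{MSE}$, $\mathrm{Err}_{MAE}$). A
zero-variance or zero-norm trajectory makes correlation/cosine undefined;
both return 0 with a warning rather than propagate `NaN` into the averages.

## Architecture selection

Because agents interact through the shared state matrix, the best
architecture for each agent is a property of the *ensemble*, not of each
gene's forecast error alone. `run_ga` searches the assignment space
$\{$FCNN, CNN, RNN$\}^n$ with a generational genetic algorithm: population
10, tournament selection of size 3, uniform crossover with probability 0.8,
per-gene uniform re-assignment mutation with probability 0.2, and a budget
of 100 fitness evaluations (repeat evaluations count). Fitness is the
negated aggregate simulation MSE, so higher is better. Two design choices
are worth making explicit: elitism of one guarantees the best-ever fitness
is non-decreasing, and trained agents are cached per (gene, architecture) so
an evaluation only trains the components it has not seen — assignments
differing in one gene cost one extra training. `fit_aes` seeds the initial
population with the three uniform single-architecture assignments, which
makes the selected mixed assignment at least as fit as the best uniform
baseline by construction.

## Perturbation inference

`infer_network` proceeds gene by gene:

1. **Steady state.** The environment runs freely until every gene's range
   over the last $m$ values falls below `eps` ($10^{-3}$ by default), then
   must hold still (per-step change below `eps`) for $m$ verification
   steps; a candidate that still drifts resumes the search. If `t_max`
   (default 500) is reached the last state is used, with a warning. The
   criterion is deliberately configurable: it trades sensitivity to slow
   transients against runtime.
2. **Perturb.** From the *same* stabilized snapshot for every gene
   (independent runs avoid carry-over), gene $i$'s row is overridden for
   $\varphi_d = m$ steps by either an *instant* function (jump to
   $\varphi_b + \varphi_w$, hold, release) or a *trapezium* function (ramp
   up over $\lfloor(\varphi_d-\varphi_p)/2\rfloor$ steps, hold the peak
   $\varphi_p$ steps plus the rounding remainder, ramp down). Defaults: the
   baseline $\varphi_b$ is the gene's value at the snapshot, the width
   $\varphi_w$ is half the gene's maximum observed expression (capped so
   the peak stays within that maximum), and $\varphi_p = 2$.
3. **Record and condense.** All genes are recorded over the instability
   interval of $\Delta t_r = 2m + \varphi_d$ steps ($m$ stability, the
   perturbation, $m$ recovery). Gene $j$'s response column is condensed to
   the regulatory value $r_{ij} = \arctan(\alpha_j)$, the arctangent of the
   OLS slope of the response against the step index — bounded in
   $(-\pi/2, \pi/2)$, exactly zero for a flat response.
4. **Calibrate.** Responder gene $j$'s activation/inhibition thresholds are
   the medians of the strictly positive / strictly negative entries of
   column $j$ of the regulatory matrix. The probability transform is
   piecewise: linear from 1 at the column minimum to $1/2$ at the
   inhibition threshold, a quadratic through $1/2$ at both thresholds and
   $0$ at $r = 0$ in between, and linear from $1/2$ at the activation
   threshold to 1 at the column maximum. When the thresholds are asymmetric
   the quadratic dips below zero on part of the inner interval; values are
   clamped to $[0,1]$. A column with no positive (or no negative) entries
   cannot calibrate that side; those entries get probability 0, with a
   warning, and the extremum falls back to $\pm\pi/2$ whenever it coincides
   with its threshold (a degenerate linear piece otherwise).
5. **Score.** $P[i,j]$ is read as "gene $i$ regulates gene $j$" — the
   orientation follows the construction (perturb $i$, observe $j$). Against
   a gold standard, AUC-ROC is computed by average ranks (ties count one
   half), excluding self-loops by default as DREAM gold standards do.

## The synthetic benchmark

`sample_network` + `simulate_dataset` provide ground-truthed inputs shaped
like GeneNetWeaver exports (e.g. 10 genes, 5 experiments of 21
observations): an Erdős–Rényi directed network (no self-loops), signed
weights of magnitude $U[0.3, 0.8]$ rescaled to spectral radius 0.9, decay
0.5, and dynamics
$x(t+1) = \mathrm{clip}_{[0,1]}\big((1-\lambda)x(t) + W^\top \tanh(x(t)) +
\varepsilon\big)$ with $\varepsilon \sim N(0, \sigma^2)$, $\sigma = 0.02$,
and a uniform random initial state per experiment. The saturating map keeps
every trajectory informative about its regulators while the noise-free
dynamics contract numerically to a fixed point — properties the test suite
verifies. This generator is deliberately *not* a kinetic ODE/SDE model:
real expression data (and GeneNetWeaver's) have slower nonlinear
transients, measurement noise that is not additive-Gaussian, and unobserved
regulators. Passing tests on this generator demonstrates that the pipeline
recovers structure planted in data its assumptions fit; it does not certify
performance on laboratory data.

A practical consequence, visible in the acceptance report: these
trajectories reach their fixed point within a few steps, so most training
windows are near-stationary, agents are rewarded mainly for autoregression,
and perturbation responses — especially their medians, which calibrate the
probability transform — sit close to the numerical noise floor. Edge
rankings on this benchmark clearly beat label-permuted controls but remain
modest in absolute terms; the per-column median calibration is the limiting
stage, since it maps noise-scale responses near the threshold to
probability one half.

## Numerical choices and degenerate inputs

* Simulated agent outputs are clipped to $[0, 1.5]$: mild extrapolation
  beyond the training scale stays visible, divergence is contained.
  Perturbation overrides are not clipped (they are bounded by construction).
* Problem sizes in the tests and the acceptance script are desk-scale by
  design: 4–10 genes, 21 observations per experiment, 5 replicate systems,
  one CPU. They exercise every code path; larger systems only change
  runtime.
* Ties in random search and the GA resolve to the first evaluated
  candidate; max-pooling ties resolve to the earlier time step.
* `perturbation_spec` validates $\varphi_b \ge 0$,
  $\varphi_b + \varphi_w \le G^{max}_i$ and
  $1 \le \varphi_p \le \varphi_d$; `make_supervised` refuses $m \ge b$;
  `auc_roc` refuses a single-class gold standard.

## Limitations

* The per-column threshold calibration makes probabilities comparable
  within a responder gene's column but only loosely across columns; AUC
  over the flattened matrix inherits that looseness.
* Signs (activation vs. inhibition) are folded into a single "regulates"
  probability; the signed regulatory matrix is returned for inspection.
* Single-gene perturbations only; combinatorial perturbations are out of
  scope.
* With tens of training samples and $n \cdot m$ inputs, agents are heavily
  over-parameterized; early stopping is the only regularizer, and learned
  couplings should be read as rankings, not effect sizes.
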