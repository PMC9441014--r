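---
title: "Models and methods behind mouec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mouec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouec)
```

`mouec` implements a complete analysis chain for parcellated resting-state
recordings of two groups measured in two sessions (a "pre" and "post"
design, as in neurofeedback-training studies): whole-brain effective
connectivity (EC) estimation with a multivariate Ornstein–Uhlenbeck (MOU)
model, machine-learning discrimination of sessions and groups with
chance-level surrogates, support-network extraction by SVM recursive feature
elimination (SVM-RFE), and intrinsic-ignition analysis of spatiotemporal
integration. This vignette explains the models, the estimation choices, and
what the synthetic validation can and cannot establish.

## The MOU model of regional activity

Regional activity $x_i(t)$ follows a linear stochastic network model

$$ dx_i = \Big( -\frac{x_i}{\tau} + \sum_{j \ne i} C_{ji}\, x_j \Big)\, dt
   + dB_i , $$

where $\tau$ is a nodal leakage time constant, $C_{ji} \ge 0$ is the directed
effective-connectivity weight from region $j$ to region $k=i$, and $dB_i$ is
white noise with diagonal covariance $\Sigma$. In matrix form the drift
Jacobian is $J = -I/\tau + C^\top$ (the package stores `ec[j, k]` as the
influence of `j` on `k`, so `J[k, j] = ec[j, k]`). The model is stationary
when every eigenvalue of $J$ has a negative real part; the package calls the
largest real part the *spectral abscissa* and refuses to simulate or solve
unstable models.

Two second-order statistics summarise the data: the zero-lag spatial
covariance $Q^0$ (FC0) and the one-TR-lagged covariance
$Q^1_{jk} = \mathrm{cov}\big(x_j(t), x_k(t + \Delta)\big)$ (FC1), with
$\Delta$ one repetition time. For a stationary MOU process,

$$ J Q^0 + Q^0 J^\top + \Sigma = 0, \qquad Q^1 = Q^0 e^{J^\top \Delta}. $$

The first is a continuous Lyapunov equation; `model_covariances()` solves it
through the eigendecomposition of $J$ (with a dense Kronecker fallback for
defective $J$ at small sizes). For $C = 0$ these reduce to the
textbook univariate results $Q^0 = \mathrm{diag}(\sigma_i \tau / 2)$ and
$Q^1 = Q^0 e^{-\Delta/\tau}$, which the test suite uses as an exact oracle.

### Fitting by Lyapunov gradient descent

`fit_mou()` tunes $C$ (restricted to a binary structural-connectivity mask
and clipped at zero) and the diagonal $\Sigma$ so that the model covariances
reproduce the empirical pair. Each iteration computes the model's
$(Q^0, Q^1)$, the deviations $\Delta Q^0, \Delta Q^1$, and the heuristic
Jacobian update

$$ \Delta J^\top \;=\; (Q^0)^{-1}\Big( \Delta Q^0 +
   (\Delta Q^1)^{\top} e^{-J^\top \Delta} \Big), $$

then moves `ec` by `rate_ec` along $\Delta J$ (masked, clipped at zero) and
$\Sigma$ by `rate_sigma` along $\mathrm{diag}(-J^\top \Delta Q^0 - \Delta
Q^0\, J)$. The lagged deviation enters in the $(t+\Delta, t)$ orientation;
with that convention the true generating model is the update's attracting
fixed point. We verified this directly: on exactly identifiable problems
(model-generated covariances) the iteration drives the normalised error to
$10^{-10}$ and the fitted weights onto the generating ones
(correlation 1.000), whereas the opposite orientation stalls at errors
around $10^{-3}$ with near-zero weight recovery because the error landscape
becomes flat in the directions that distinguish the two members of a
reciprocal edge pair.

Numerical safeguards, chosen after observing the optimiser's behaviour on
synthetic problems:

* The iteration runs at fixed learning rates (defaults `rate_ec = 5e-4`,
  `rate_sigma = 0.05`). The update is a fixed-point heuristic rather than a
  strict gradient, so the error may rise transiently while still descending
  overall; strict monotone line search was tried and systematically stopped
  at such bumps, far from identification.
* If a step destabilises the model or blows the error beyond twice the best
  value seen, the optimiser reverts to the best iterate and halves the rate.
* Stopping: `max_iter` (default 10,000) or no strict improvement of the best
  error for `patience` consecutive iterations (default 2,000). Deep patience
  matters: identification of edge *direction* happens late in the descent,
  long after the error looks converged on a coarse scale.
* The model's $Q^0$ is positive definite by construction (diagonal
  $\Sigma > 0$), so the linear solve in the update is well posed; a
  pseudo-inverse fallback covers near-singular cases and is flagged in the
  fit report.
* $\tau$ is held fixed during optimisation, taken from `estimate_tau()`: the
  average across regions of the log-linear decay rate of the empirical
  autocovariance over lags 1–2 TR. On coupled networks this is an
  *effective* decay constant (network feedback slows the marginal
  autocovariance), which is exactly the quantity the model's leakage term
  should absorb; on uncoupled simulations it recovers the nominal $\tau$.

The per-iteration cost is one nonsymmetric eigendecomposition, reused for
the Lyapunov solution and both matrix exponentials, so fits scale as
$O(n^3)$ per iteration; the loop is compiled (RcppArmadillo). The exported
`lyapunov_step()` is the literal single fixed-rate step, and `fit_mou(...,
engine = "r")` runs the same arithmetic in pure R; a test pins the two
engines to each other.

### What parameter recovery shows

With exact (model-generated) covariances, 10-region models on 20%-density
skeletons are recovered essentially perfectly (median weight correlation
1.00). From single simulated sessions of 500 samples the median recovery is
about 0.8: the remaining error is covariance sampling noise, not optimiser
failure. Recovery degrades with denser skeletons (more parameters per
observed covariance entry) and with models closer to instability (slower
mixing means fewer effectively independent samples); at the full 116-region,
235-volume scale of a realistic session, per-edge recovery is weak — which
is why the cohort-level analyses below rely on *contrasts* between sessions
rather than on absolute weights.

## Synthetic cohorts

`generate_cohort()` emulates the study design the pipeline targets: group A
(17 subjects) and group B (16), two sessions each, 116 regions, TR 2 s, 235
volumes; a common random structural skeleton at 30% density; and a known set
of 5 directed edges whose weights change between sessions in group A only
(multiplicatively by `1 + perturbation_scale`, so the mask support never
changes). Design choices:

* Subject weights are jittered (±20%) around a shared group template,
  mirroring the high between-subject similarity of real connectomes; each
  subject's weights are rescaled so that even the perturbed Jacobian keeps a
  stability margin (spectral abscissa $-0.1/\tau$).
* Sessions are integrated by Euler–Maruyama at `dt = TR/20` — small enough
  that the lag-1 autocovariance of a univariate simulation matches
  $e^{-\mathrm{TR}/\tau}$ within 2% — after a discarded burn-in of $20\tau$
  seconds; every subject-session has its own derived random stream.
* The noise covariance is diagonal with mild heterogeneity (uniform within
  ±10%).

The generator does **not** include a hemodynamic forward model, head motion,
physiological nuisance structure, scanner drift, or spatial smoothing-induced
correlations: the MOU output *is* the parcellated signal, matching the model
being fitted. Passing tests on these cohorts therefore demonstrates the
correctness and power of the estimation/classification machinery under the
model's own assumptions, not robustness to the full messiness of real fMRI.

The effect size of the planted perturbation is deliberately large
(the default `perturbation_scale = 20`, i.e. the 5 perturbed
weights grow 21-fold). At 116 regions, a stability-constrained network
operates in a weak-coupling regime where a single edge's weight is ~0.007;
doubling such an edge moves any given covariance entry by well under one
sampling standard deviation of a 235-volume session, so *no* method could
detect it per subject. The chosen scale makes the per-feature effect size
(Cohen's d of fitted-EC features) of order 2–4 — strong but honest: the
validation asks whether the chain localises and classifies a real, visible
effect, not whether it can beat an information-theoretic wall.

## Classification and surrogates

Feature vectors per session: the strictly lower triangle for symmetric FC
(covariance of the band-passed signal) and SC matrices (6,670 features at
116 regions), and the mask-restricted entries of the directed EC matrix.
Each sample is z-scored across its features. Classifiers: 1-nearest
neighbour under distance $1 - r$ (Pearson), ties to the lowest training
index, and a linear SVM with fixed cost 1. Evaluation repeats a random
80/20 train/test split 50 times; chance level comes from label-shuffled
surrogates (a fresh permutation per split), and accuracy distributions are
compared with the two-sided Wilcoxon rank-sum test.

One property of this protocol deserves attention: with small unstratified
test sets, the training class balance anti-correlates with the test
composition, so a signal-free classifier scores *below* 0.5 on average (the
majority-class artifact). The artifact affects real and surrogate runs
equally, which is why the package's acceptance checks compare real accuracy
*against the surrogate mean* rather than against 0.5. Splits are by session
(the sample unit); a subject-level split mode is available because the
within-group task places both sessions of a subject in the pool, and the
correlated pair inflates the artifact for 1NN.

## SVM-RFE support network

`rfe_ranking()` eliminates 5% of surviving features per iteration while more
than 200 remain, then one per iteration; rank 1 is the last survivor.
`select_support_network()` repeats (by default 10 times): random 80/20
split, ranking on the training samples, and a held-out accuracy trace over
prefix sizes (every size up to 200, geometric steps above). The selected
size is the smallest prefix whose mean accuracy across repetitions is within
$10^{-6}$ of the maximum; edge identities come from the consensus (mean)
ranking across repetitions. The mean-trace reading keeps the subset size
stable across random splits; selecting per repetition and aggregating was
the ambiguous alternative and tends to overfit single splits.

## Intrinsic ignition

Signals are band-passed to 0.04–0.07 Hz, and instantaneous phases
$\varphi_j(t)$ are taken from the analytic signal. Pairwise phase locking is
$P_{jk}(t) = e^{-3\,|\varphi_j(t) - \varphi_k(t)|}$ with the difference
wrapped to the circular distance in $[0, \pi]$ (the wrapping is the
package's reading of the plain absolute value: without it, equal phases
separated by $2\pi$ would count as desynchronised). Driving events are
rising crossings of $z = 1$ of each region's standardised signal — one event
per excursion, so sluggish band-passed signals do not inflate event counts.
For each event, every time point of a 4-TR window contributes the size of
the largest connected component of the thresholded matrix $P \ge 0.5$
(threshold exposed as `binarize_threshold`; a z-score-style threshold is not
well defined for values in $(0,1]$, so the event threshold and the
binarisation threshold are deliberately two separate parameters).
Integration is the window mean of component sizes divided by the number of
analysed nodes, so whole-brain and subnetwork analyses are comparable; the
raw size is `integration * |node_subset|`. Per region, IDMI is the mean of
integration over the region's events and metastability its standard
deviation; regions with fewer than two usable events are flagged and
excluded from aggregates. `compare_ignition()` aggregates each
subject-session to its mean over analysed regions and applies a paired
signed-rank (pre vs post) or rank-sum (between groups) test per measure —
the subject-level reading; all-zero paired differences are reported as
non-significant rather than an error.

## The pipeline

`run_pipeline()` chains the stages on one cohort: group-average SC masks
(top 30% of undirected pairs by mean weight, ties broken lexicographically)
plus their intersection for between-group EC features; per-session
band-passing (0.01–0.07 Hz — the model band; a second-order zero-phase
Butterworth), covariance pair, $\tau$ estimate and MOU fit; within-group and
between-group classification with surrogates; SVM-RFE on the first group's
EC features; ignition profiles whole-brain and on the support-network nodes.
Every stochastic stage draws its seed deterministically from the global seed
and a stage tag, so a rerun with the same configuration produces a
byte-identical JSON report (timings are logged to the console, never stored
in the report).

### Problem sizes used in the validation suite

The bundled smoke configuration runs 8+8 subjects at 30 regions and 120
volumes with 120-iteration fits — small enough to verify the full chain and
its determinism quickly. The cohort-level acceptance checks run the full
17+16-subject, 116-region, 235-volume design with 300-iteration fits: at
this size the error plateau is reached long before full identification, and
longer fits were observed to change session *contrasts* negligibly while
multiplying runtime. The parameter-recovery study uses 10-region,
20%-density models where full-depth optimisation (10,000 iterations) is
cheap and identification is the point.

## Known limitations

* The MOU model is linear with diagonal noise; it cannot represent
  state-dependent coupling, and the EC weights are constrained nonnegative.
* $\tau$ is global across regions (the estimator averages nodes), as in the
  model being emulated.
* Recovery of individual EC weights at 116 regions from a single 235-volume
  session is intrinsically noisy; analyses should be read at the level of
  session/group contrasts.
* The SC mask is treated as ground truth topology; false negatives in the
  mask remove edges from the model space entirely.
* The ignition statistics use overlapping windows when events are close
  together; each event is scored independently.
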