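---
title: "Process models of confidence forced-choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process models of confidence forced-choice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfchoice)
```

## The task and the decision problem

An observer is briefly shown a cloud of 2 or 5 dots sampled from a 2D
circular symmetric Gaussian whose horizontal mean sits at one of seven
offsets ($\pm4, \pm2, \pm1, 0$ deg) and whose SD is 1.5, 2 or 2.5 deg.
They judge whether the generating mean lies left or right of centre (the
Type 1 judgement).  After every two judgements they report which of the
two decisions they are more confident about (the Type 2, confidence
forced-choice judgement) — a relative report that sidesteps
over/under-confidence biases and ceiling effects on rating scales.  A
default session crosses all 42 conditions 20 times: 840 perceptual and
420 confidence judgements; five sessions give 4200 and 2100.

Because dot count and dot spread are manipulated independently, the
observer faces joint uncertainty about the generating mean *and* its
precision.  The package models the observer as inferring both: per-dot
measurements $x_i = d_i + \varepsilon_i$, $\varepsilon_i \sim
\mathcal{N}(0, \sigma_\mathrm{dot}^2)$, carry combined per-dot precision
$\tau_\mathrm{comb} = 1/(\sigma_\mathrm{cloud}^2 +
\sigma_\mathrm{dot}^2)$, and the posterior over
$(\mu_\mathrm{cloud}, \tau_\mathrm{cloud})$ is formed either under a
centred normal-gamma prior ($\mu_0 = 0$, $\kappa_0 = 0.68$,
$\alpha_0 = 3.84$, $\beta_0 = 13.48$, moment-matched to the true
stimulus statistics and taken as given) or under a flat prior (uniform
over mean and spread, i.e. the normalised likelihood).  The Type 1
decision compares the marginal-posterior mass right of the criterion
$k_1$ with 1/2, lapsing with rate $\lambda$.

## Numerical backbone: the marginal posterior as a Gaussian mixture

The conjugate update gives conditional normal-gamma parameters
$(\mu_p, \kappa_p, \alpha_p, \beta_p)$ at each $\tau_\mathrm{cloud}$,
but $\kappa_p$ and $\beta_p$ retain a $\tau_\mathrm{cloud}$ dependence
(the per-dot precision mixes the two variance sources), so the usual
closed-form Student-$t$ marginal does not apply.  We therefore
marginalise numerically on a grid uniform in $\sigma_\mathrm{cloud}$
over $[0.5, 5]$ deg (201 points by default).  Two points deserve
emphasis:

* **Kernel, not normalised density, per precision value.**  Because
  $\beta_p$ depends on $\tau_\mathrm{cloud}$, evaluating the full
  normal-gamma *density* (with its $\beta_p^{\alpha_p}$ normaliser) at
  each grid point would not reproduce likelihood × prior.  The
  conditional-parameter route instead evaluates the joint as
  $w(\tau)\,\mathcal{N}(\mu \mid \mu_p, (\kappa_p\tau)^{-1})$ with
  $w(\tau) \propto \sqrt{\kappa_0/\kappa_p}\,\tau^{\alpha_p - 1}
  e^{-\beta_p \tau}$.  An independent oracle — direct normalisation of
  likelihood × prior on the full 2-D grid — is implemented alongside and
  the two routes are required to agree to $10^{-4}$ in density (they
  agree to machine precision in practice).
* **Closed-form mixture summaries.**  At fixed dot count, sensory noise
  and prior variant, the marginal posterior is a Gaussian mixture whose
  component means are linear in the measured centroid $\bar{x}$ and
  whose log-weights are quadratic in $\bar{x}$ and linear in the
  measured variance $s^2$.  Category evidence, posterior moments and the
  posterior mode (by mean-shift iteration) therefore vectorise over
  hundreds of thousands of measurement draws, which is what makes
  simulation-based likelihoods tractable.  Inside the fitting loops the
  centred-variant summaries are additionally interpolated from bilinear
  lookup tables over $(\bar{x}, s_\mathrm{emp})$ (0.2 deg × 0.25 deg
  node spacing; signed log odds are tabled rather than probabilities
  because they are near-linear in $\bar{x}$).  Table error is about
  $2\times10^{-4}$ on each summary, negligible against confidence noise;
  the `use_tables` config switch disables them.

The mu grid spans $\pm20$ deg at 0.02 deg steps.  The flat-prior
marginal is a fat-tailed scale mixture, and a narrower grid (e.g.
$\pm12$ deg) truncates up to $10^{-4}$ of its mass for in-range stimuli;
$\pm20$ keeps edge density below the package's $10^{-4}$ diagnostic,
which errors rather than silently truncating.

A related subtlety: the mode and the probability metric of the Type 1
decision ("posterior mode right of $k_1$" versus "$p(C=R) > 1/2$")
coincide exactly at $k_1 = 0$ — every mixture component shares the sign
of $\bar{x}$ — but for $k_1 \neq 0$ the mildly asymmetric marginal lets
the mode and the median straddle the criterion in a narrow band of
$\bar{x}$.  Fitted parameter estimates are identical in practice and the
likelihoods near-identical; the package computes both metrics genuinely
rather than aliasing one to the other.

## The twelve confidence models

All models share the Type 1 front end and differ in the confidence
decision variable $w$ compared across the two intervals of a pair
(interval bias $k_2$, decision rule $w_2 + k_2 > w_1$ or $w + k_2 > 0$
for difference-type variables, and a Type 2 lapse equal to the Type 1
rate):

* **Ideal** — $w = p(\text{reported side correct})$, no noise, no bias.
  On lapse trials the observer is aware of the lapse, so the reported
  side carries the *minority* probability.
* **Basic-Probability** — early beta noise
  $w \sim \mathrm{Beta}(\nu p, \nu(1-p))$; $\nu \to \infty$ recovers the
  Ideal comparison.
* **Probability-Difference** — late Gaussian noise on $p_2 - p_1$.
* **Log-Probability-Ratio** — $w = |\log\frac{p}{1-p} + \epsilon|$.
* **Unscaled-Distance** — $w = |\hat\mu - k_1 + \epsilon|$ (extended-SDT
  style distance from criterion).
* **Scaled-Distance** — $w = |(\hat\mu - k_1)/\hat\sigma + \epsilon|$
  (signal-to-noise scaling by the posterior spread).
* **Heuristic** — a weighted sum of stimulus cues computed from the
  noisy measurements: $w = z(\Delta|\mu_c - k_1|) + \beta_1 z(\Delta N)
  + \beta_2 z(\Delta(1/\sigma_\mathrm{emp})) + \epsilon$.  Predictors
  are z-scored across all pairs of the dataset and the position weight
  is fixed at 1, so the fitted $\beta$s are directly comparable.  The
  inverse-spread difference is oriented so that the interval with the
  *smaller* measured spread gains evidence when $\beta_2 > 0$, matching
  the direction of the fitted coefficients.  $\sigma_\mathrm{emp}$ is
  clipped at 0.01 deg before inversion (2-dot clouds can have
  arbitrarily small sample spread).

Flat/centred prior variants double every model except the Ideal
observer (centred by definition) and the Heuristic model (no posterior),
giving twelve.  Free Type 2 parameters: none (Ideal), two
($\nu$ or $\sigma_\mathrm{conf}$, plus $k_2$), four (Heuristic).
Probabilities are clipped to $[10^{-9}, 1-10^{-9}]$ before logs or beta
parameterisation.

Two open readings were resolved as follows.  The Heuristic model's cue
inputs are the *noisy measured* centroid and spread (the fitting
procedure conditions measurements on the Type 1 response, which only
makes sense if the confidence stage consumes the same measurements); a
noiseless, screen-based reading can be emulated by setting
$\sigma_\mathrm{dot}$ near zero.  And the Basic-Probability decision
rule is applied on the raw probability scale as printed, although
$w_2 + k_2$ can then leave $[0, 1]$; $k_2$ simply shifts the comparison.

A note on z-scoring: with 2-dot clouds the sample spread can be tiny, so
$1/\sigma_\mathrm{emp}$ is heavy-tailed and its standard deviation is
dominated by rare near-degenerate clouds.  Z-scoring by that SD makes
the *effective* raw-scale quality weight small even for sizeable
$\beta_2$ — a property of the generator worth keeping in mind when
interpreting quality effects at small trial counts.

## Fitting

Fitting is two-step, as the response structure dictates.  **Type 1**
parameters $(\sigma_\mathrm{dot}, k_1, \lambda)$ are fit by brute-force
grid search on the Bernoulli likelihood of the left/right responses,
with per-trial response probabilities estimated from simulated
measurement draws.  The same standard-normal draws are reused across all
grid points (common random numbers), and the centred-variant decision is
reduced to a one-dimensional boundary $x_\mathrm{crit}(s_\mathrm{emp})$
per criterion — category evidence is monotone in the measured centroid
(a tested property) — so the grid search stays cheap.  Default grids:
$\sigma_\mathrm{dot} \in [0.2, 3]$ step 0.05, $k_1 \in [-1.5, 1.5]$ step
0.05, $\lambda \in [0, 0.1]$ step 0.005; boundary optima raise a warning
prompting grid extension.

**Type 2** parameters are fit with the Type 1 parameters frozen.  For
every trial a *measurement bank* is built by rejection sampling:
measurement draws whose (lapse-free) decision reproduces the observed
response.  Trials whose response cannot be reproduced within the
sampling cap — lapses on easy stimuli — are flagged and routed through
the lapse-aware branch (their evidence uses unconditioned draws, and the
probability models consume the reported side's minority probability).
The pair-choice probability is computed *analytically* given the bank
draws: an error-function for the late-Gaussian difference rules and
Gauss–Hermite quadrature over the folded-Gaussian comparisons (both
implemented in C++, cross-checked against plain-R references and
Monte-Carlo oracles).  The resulting simulated likelihood is
deterministic in the parameters, so a bounded derivative-free simplex
search (Nelder–Mead on a logistic-transformed box, Latin-hypercube
multistarts, bounds: $\nu$ and $\sigma_\mathrm{conf}$ log-spaced in
$[10^{-3}, 10^3]$, $k_2 \in [-5, 5]$, $\beta \in [-10, 10]$) behaves
well.  The Ideal model has no free parameters and is evaluated once.

The Basic-Probability model needs its own optimisation scheme.  Its
beta-versus-beta comparison is evaluated through per-draw quantile
ladders (midpoint levels for the interval-2 average, extra near-tail
levels anchoring a piecewise-linear CDF of interval 1); ladders must be
rebuilt whenever $\nu$ changes, and interpolating them across a $\nu$
grid leaves kinks that stall a simplex.  $\nu$ is therefore profiled on
a $\log_{10}$ grid with exact (cached) ladders per knot, $k_2$ scanned
on a grid and polished by Brent's method inside the winning bracket, and
the best knot refined by a quadratic step — still bounded and
derivative-free.  The ladder evaluation agrees with direct
beta-quadrature likelihoods to within about one log-likelihood unit at
420 pairs, comfortably inside the AICc differences of interest, and the
public [confidence_choice_prob()] API keeps the exact quadrature.  Models are compared by
$\mathrm{AICc} = 2\,\mathrm{nll} + 2k + 2k(k+1)/(n-k-1)$ with $n$ the
number of confidence pairs.

The study being re-implemented did not report its simulation counts,
bank sizes or optimiser settings; the defaults here (1000 draws per
trial for Type 1 probabilities, 200-sample banks, 10 multistarts) are
engineering choices sized so that the Monte-Carlo noise floor of the
likelihood sits well below the AICc differences of interest, and they
are recorded in every output's configuration provenance.  The `desk`
and `smoke` presets trade resolution for runtime in interactive use and
tests; the test suite states its problem sizes explicitly as package
choices.

## Synthetic observers and what they do (not) cover

`simulate_observer()` is the package's data generator and the stand-in
for the study's raw data.  It reproduces the experiment's structure
exactly — balanced interleaved schedules, consecutive-trial pairing
(the realisation of "pairings left to chance" under a shuffled trial
list), exact session repeats sharing a stimulus stream while sensory
and confidence noise stay fresh per pass, `mu_cloud = 0` trials
assigned a random true side, vertical dot coordinates generated but
inferentially inert.  Default generator parameters for recovery
experiments sit at the reported group means where available
($\sigma_\mathrm{dot} = 1.0$ between the reported 0.90–1.05;
Heuristic $\beta_1 = 0.68$, $\beta_2 = 0.38$,
$\sigma_\mathrm{conf} = 1.20$, $k_2 = 0.13$) and otherwise at values a
practitioner would call realistic for each evidence scale
(Basic-Probability $\nu = 20$, i.e. beta-noise SD $\approx 0.05$ at
$p = 0.95$; Probability-Difference $\sigma_\mathrm{conf} = 0.1$ on the
$[-1,1]$ probability-difference scale; Log-Probability-Ratio 1.5 on the
log-odds scale; Unscaled-Distance 1.0 deg; Scaled-Distance 1.2 SNR
units; $k_2 = 0.1$, or 0.05 on the probability-difference scale).
These were fixed once, before any acceptance outcome was inspected.

What the simulations deliberately do **not** emulate: serial
dependence, learning or fatigue across sessions, memory effects in the
forced choice, probability distortion, and any cross-pass correlation
of internal noise — the models assume independent noise across passes,
and that assumption is exactly what the agreement analysis tests.  A
`rho` parameter exists solely to *inject* cross-pass confidence-noise
correlation and verify that the machinery detects super-model
consistency; it is never part of a fitted model.  Passing tests
therefore certify the pipeline's internal consistency on data that obey
the models, not that human data do.

## Confidence agreement

With repeated identical sessions, agreement is scored per pair as the
proportion of passes giving the most frequent choice (4 of 5 passes
agreeing is 80%).  Model-predicted agreement repeats the full N-pass
simulation (100 datasets by default) under the fitted parameters and
reports the distribution of agreement counts with ±2 SD bands; the
observed-versus-predicted comparison takes, per observer, the
proportion of pairs at the highest possible count and applies a
two-sided Wilcoxon signed-rank test to the differences.  Ties at even
pass counts are recorded as agreement 0.5 and flagged (the tie handling
is unspecified in the source study, which had 3-, 4- and 5-pass
observers).  For the Basic-Probability model a 1%-SD late-noise variant
(`late_sd = 0.01`) is provided: the raw model discriminates
probability differences like 0.985 versus 0.998 that no human could,
and a whiff of late noise brings its predicted agreement in line with
the other noisy models.

## Scale presets and reproducibility

Every stochastic stage derives its stream from one master seed
(`derive_seed()`), so identical inputs give bit-identical outputs, and
configuration hashes (`config_hash()`) are invariant to key order.  The
`full` preset reproduces study-scale analyses and is the only preset
intended to approach the printed recovery statistics; a full 12-model ×
16-observer × 10-dataset recovery is an overnight computation on one
CPU.  `desk` and `smoke` shrink grids, draws and optimiser effort for
interactive work and continuous testing; with them the recovery
machinery is validated through diagonal dominance of the confusion
matrix at reduced trial counts rather than through the printed rates.
Reduced-scale parameter-recovery tolerances were calibrated once from
pilot repeat-fit spread at the test's own scale and then frozen.

## Known limitations

* The centred-prior constants are hard-coded from the source study;
  independent moment matching of the discrete stimulus marginals is not
  attempted, and the prior is not refit to data.
* No accumulation-to-bound (reaction-time) models; the task's brief
  presentations do not constrain them.
* The Type 2 likelihood treats flagged (response-inconsistent) trials
  through the lapse branch with unconditioned measurements — a
  pragmatic approximation to full marginalisation over lapse
  occurrence.
* Model-recovery rates at reduced scale are systematically below
  study-scale rates; flat- versus centred-prior variants are the least
  separable pair, as the source study also observed.
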