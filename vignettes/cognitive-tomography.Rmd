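---
title: "Inferring internal models of sequence learning from response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring internal models of sequence learning from response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtomo)
```

## The problem

In the Alternating Serial Reaction Time (ASRT) task, a stimulus appears at
one of four locations and the participant presses the matching key. Unknown
to them, a deterministic 4-element pattern alternates with uniformly random
trials (`2r4r3r1r...`), in blocks of 85 stimuli whose first five trials are
random warm-ups. People respond faster to stimuli they implicitly expect, so
the trial-by-trial response times carry information about the *internal
model* each participant has formed of the sequence statistics.

`cogtomo` treats the participant as a Bayesian filter: their internal model
is a discrete hidden Markov model (HMM) with transition matrix $\pi$ and
emission matrix $\phi$ over the four stimuli. Before each trial the filter
supplies a predictive distribution over the next stimulus,
$$p(y_{t+1}\mid y_{1:t}) = \sum_{s_t,\,s_{t+1}} \phi_{s_{t+1},y_{t+1}}\,
\pi_{s_t,s_{t+1}}\,\hat s_t(s_t),$$
where $\hat s_t$ is the filtered belief over latent states. The subjective
probability $p_n$ of the stimulus that actually appears drives the response
time through the LATER model,
$$\mathrm{RT}_n = \theta_0 + \frac{-\log p_n}{r_n},\qquad
r_n \sim \mathcal N(\mu,\sigma)\ \text{truncated to } r_n > 0 .$$
The experimenter then performs Bayesian inference over the participant's
$(\pi, \phi, \theta_0, \mu, \sigma)$ given stimuli and response times — a
*doubly Bayesian* problem, since the inferred object is itself a Bayesian
filter.

## Reference models

Three fixed-structure alternatives anchor the comparison:

* **Ideal observer** — the true generative process: an 8-state HMM
  (Pattern1, Random1, ..., Pattern4, Random4) in which pattern states emit
  their element deterministically and random states emit uniformly
  (`ideal_observer()`). Its one-step observable conditionals are uniform,
  which is why a first-order model can learn nothing from this task.
* **Markov model** — an observation-level first-order model, an HMM with
  identity emissions (`markov_as_hmm()`); the parsimonious inductive bias
  that dominates early learning.
* **Trigram (triplet) model** — the field-standard ASRT measure: the next
  stimulus is predicted to be the pattern successor of the stimulus two
  trials back with probability 0.625, each alternative 0.125, and 0.25 on
  the first two trials of a block. These values are conventional labels for
  the high/low classification, but they also equal the analytic
  continuation probabilities of the generative process:
  `trigram_continuation_probs()` derives them by exact marginalization over
  trial parity ($\tfrac12\cdot 1 + \tfrac12\cdot\tfrac14 = 0.625$) rather
  than asserting the constants.

A caveat that matters in practice: the *exact* ideal observer assigns
probability zero to stimuli that contradict the alternation, and warm-up
trials genuinely do contradict it. Filtering it over a full session can
therefore raise a zero-probability error — by design, rather than silently
renormalizing. Whenever the ideal observer is used as a *filtering* model on
data that include warm-ups (`fit_fixed_model()`, pipelines), we pass it
through `soften_hmm()` with a 1–2% uniform floor. The empirical consequence
of warm-ups is also visible in the triplet statistics: among trials whose
two-back window lies inside the alternating part, 62.5% are high triplets,
but averaged over *all* defined trials of an 85-trial block the fraction is
$(39 + 44/4)/83 \approx 0.602$, because windows touching warm-ups are at
chance.

## Priors and inference

The nonparametric prior over transition structure is implemented as a finite
truncation at `k_max` states (default 12, comfortably above the 8-state
ideal observer) with a remainder component: each row of $\pi$ has prior
$\mathrm{Dirichlet}(\alpha_0/K, \ldots, \alpha_0/K, \alpha_0/K\cdot\epsilon)$,
emission rows $\mathrm{Dirichlet}(0.8, 0.8, 0.8, 0.8)$, and concentrations
$\alpha = 1.3$, $\gamma = 3.8$ (the top-level concentration is carried as
metadata of the truncated construction; the full stick-breaking hierarchy is
not expanded). $\epsilon$ is the *slicing variable*, resampled from
$\mathrm{Uniform}(0.02, 0.2)$ at every outer step; during filtering only the
states covering the belief's $1-\epsilon$ support are retained (and the
truncated belief renormalized — carrying the remainder mass instead would
also be defensible, but renormalization keeps the filter a proper
distribution). We read the $\epsilon$ appearing in the row prior and the
slicing variable as the same quantity.

The LATER priors are Gamma distributions interpreted as shape–rate *with
time in seconds*: $\theta_0 \sim \Gamma(1, 10)$ (mean 0.1 s),
$\mu \sim \Gamma(1, 0.1)$ (mean 10 s$^{-1}$),
$\sigma \sim \Gamma(1, 0.01)$. This is the only reading that puts prior mass
on human response-time scales; files store milliseconds and I/O converts.
The paper-family notation uses $\tau_0$ and $\theta_0$ interchangeably for
the offset; we treat them as the same parameter. Truncation of the rate is
applied at $r > 0$, the simplest scheme that keeps response times positive
and the density closed-form:
$$f(\mathrm{rt}) = \frac{\varphi\!\big((x/d - \mu)/\sigma\big)}
{\sigma\,\Phi(\mu/\sigma)} \cdot \frac{x}{d^2},
\qquad x = -\log p,\; d = \mathrm{rt}-\theta_0 > 0 .$$
Predictive probabilities are floored at $10^{-6}$ before taking logs so that
point predictions and likelihoods stay finite.

Sampling mixes an outer Gibbs move over $\epsilon$ with gradient-based
No-U-Turn (NUTS) updates of all continuous parameters. Because no
probabilistic-programming backend expresses a forward-filtered HMM likelihood
feeding a reciprocal-normal response-time density, the package implements
the likelihood and its reverse-mode analytic gradient in C++
(`src/ct_kernel.cpp`) and a standard NUTS with dual-averaging step-size
adaptation and a diagonal mass matrix in R. Numerical choices worth knowing:

* Simplex rows are parameterized by anchored softmax; with a
  $\mathrm{Dirichlet}(a)$ prior the density plus transform Jacobian is
  $\sum_k a_k \log x_k + \text{const}$, with gradient $a_j - (\sum_k a_k)
  x_j$ — cheap and exact.
* $\theta_0, \mu, \sigma$ are sampled on the log scale.
* The initial belief is the stationary distribution of $\pi$ (the least
  informative dynamically consistent choice; the paper family leaves it
  unstated) and is treated as a constant in the gradient. Inexact gradients
  only affect proposal efficiency — Metropolis acceptance uses the exact
  density — and the filter resolves the pattern phase within one cycle
  regardless of the starting belief.
* Beliefs are *not* reset at block boundaries, and warm-up and error-trial
  stimuli are filtered like any others; only their response times are
  excluded from the likelihood (together with responses faster than 180 ms,
  which are cut rather than modelled).
* The first half of each chain adapts (step size throughout, the diagonal
  metric once at the midpoint of warm-up from the later half of the
  accumulated draws) and is also the half discarded by `diagnostics()`.
* Chains are initialized from the priors, with the LATER draw clamped to
  the physiological range so chains start at finite likelihood; chain $c$
  uses seed `seed + c`, restarts (after a divergent log joint) shift the
  seed by 1000.

Two presets are provided. The `full` preset is the reference schedule
(4 chains × 1600 outer × 30 inner NUTS steps, tree depth 8). The `desk`
preset (2 × 200 × 5) is for interactive work and is what the test suite
runs; it caps the NUTS doubling at depth 5, which on pilot runs cut the cost
roughly fourfold at a negligible loss of held-out recovery (subjective
probability recovery 0.92 vs 0.94 on the same synthetic participant). For
prediction, the last 60 unique samples of each chain are averaged —
performance saturates near that number — and predictions never feed measured
response times back into the belief.

Within a fit, $\pi$ and $\phi$ are constant across trials; only the belief
$\hat s_t$ evolves. Fits are per participant and per session; the standard
protocol trains on blocks 11–20 and evaluates on blocks 1–10.

## Synthetic participants

The validation harness simulates participants exactly as the behavioural
model assumes. Three ground-truth internal models emulate increasing
experience: `early` is a near-Markov 4-state model (identity-like emissions,
mildly structured transitions), `middle` is the 8-state skeleton with
heavily softened parameters, `late` the ideal observer with a light
softening. Their KL divergence from the task's true trial probabilities is
ordered early > middle > late by construction, which is what "increasing
experience" means operationally here. An optional `stimulus_fit` mode
derives the three models instead by fitting the truncated-HDP HMM to bare
stimulus streams of 640/1280/2400 trials (`fit_stimulus_model()`), emulating
learning by exposure.

Response times are drawn through the LATER sampler at each trial's
subjective probability of the realized stimulus. The default grid crosses
$\theta_0 \in \{0.12, 0.18, 0.24\}$ s, $\mu \in \{6, 8, 10\}$ s$^{-1}$,
$\sigma \in \{1, 2, 3\}$ s$^{-1}$ — 27 cells per model, 81 datasets for
three models, with simulated response-time standard deviations bracketing
the range typical of human ASRT sessions (roughly 60–250 ms). Error trials
are not part of the generative study; an optional rule
(`simulate_participant(..., error_rate = )`) injects errors with probability
proportional to $1 - p_n$ so the error-rank and ROC analyses can be
exercised on semi-synthetic data. Synthetic generation applies no 180 ms
floor; the fit applies the standard mask.

What passing recovery tests shows — and what it does not: the simulator
realizes the model's own assumptions (reciprocal-normal noise, a fixed
internal model within a session, correct-only responses). Real participants
drift within sessions, produce express responses and errors, and may violate
the LATER form (occasionally bimodal rate residuals); recovery on this
harness validates the inference machinery, not the behavioural model.

## Evaluation conventions

* `r2_score()` reports both the squared Pearson correlation (`corr2`,
  default — required when predictions are an affine-free binary code, as for
  the trigram model) and $1 - \mathrm{SSE}/\mathrm{SST}$ (`ssr`, which can
  be negative). Batch outputs emit both.
* `kl_mean()` floors model probabilities at $10^{-9}$ and renormalizes;
  ground truth for ASRT is probability 1 on pattern elements and 0.25 on
  random trials.
* Rank analyses split top ties fractionally, making chance exactly 0.25.
* The ROC for error prediction scores each trial by the subjective
  probability of the realized stimulus; AUC is the trapezoid rule and equals
  the Mann–Whitney statistic with ties counted one half. The trigram model
  contributes exactly two interior points.
* The higher-order learning score compares matched high-triplet windows that
  share the same observed three stimuli but differ in whether the third
  (and first) element is a pattern or a random trial. Windows straddling
  block boundaries are excluded, matching is on the full observed triplet
  identity, and the score is positive when pattern trials are answered
  faster; "inverse learning" therefore appears as a negative score. The
  trigram model scores exactly zero by construction.
* `decompose_ct()` is an ordinary least-squares decomposition of one
  model's trial-by-trial predictions into Markov and ideal-observer
  components plus an offset; collinear predictors raise an error carrying
  the condition number.
* `map_rt()` is the plug-in prediction $\theta_0 + (-\log p)/\mu$ by
  default. The exact density mode sits at rate
  $w^\* = \big(\mu + \sqrt{\mu^2 + 8\sigma^2}\big)/2$, i.e. the plug-in
  overestimates the rise time by about 10% at $\sigma/\mu = 0.25$; the
  two agree as $\sigma/\mu \to 0$. The plug-in is kept as the default
  because it is the conditional prediction conventionally used with LATER
  and is monotone in $p$ at any noise level.

## Problem sizes used by the tests

The suite runs entirely on the desk preset: `k_max = 8`, 20-block sessions
with blocks 11–20 for training and 1–10 held out (the reduced validation
grid uses 6 blocks, training on 3), three replicate seeds for the stochastic
identification and recovery checks, and 200 random instances for the
filtering-versus-enumeration oracle. These sizes keep the full suite in the
tens of minutes on a single CPU while leaving every qualitative conclusion
(recovery above 0.8, correct model identification, metric identities)
comfortably away from its threshold.

## Known limitations

* The truncated prior is a pragmatic stand-in for the full hierarchical
  Dirichlet process; posterior mass on state counts near `k_max` signals
  that the truncation should be raised.
* The sampler treats the slice-truncated likelihood as the target between
  $\epsilon$-moves; like the original beam-sampling scheme this is an
  approximate (annealed) construction, not an exact joint sampler.
* The LATER likelihood conditions on correct responses; choice errors are
  masked, not modelled, so error rates carry no information in the fit.
* Stimulus-only fits (`fit_stimulus_model()`, the `stimulus_fit` mode of the
  ground-truth constructor) face a heavily multimodal posterior; at desk
  schedules single chains routinely settle in different modes, so sharp
  pattern predictions and monotone occupied-state growth with exposure
  should only be expected from the full sampling schedule with several
  chains.
* Occupied-state diagnostics count states by time-averaged belief mass
  (threshold 0.01), a heuristic summary rather than an identified quantity —
  state labels are not identifiable and predictions are the only
  permutation-invariant readout.
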