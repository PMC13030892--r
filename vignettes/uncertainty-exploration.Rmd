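---
title: "Modelling uncertainty-guided exploration in the two-deck card task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling uncertainty-guided exploration in the two-deck card task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardexplore)
```

## The task and the observer model

The environment simulated by `cardexplore` is a room with four tables, each
holding two decks of cards. Each deck $i$ has a hidden proportion
$\pi_i$ of orange (versus blue) cards, and the learner's goal on each table
is the sign of the proportion difference,
$\theta = \mathrm{sgn}(\pi_1 - \pi_2)$: which deck is richer in the target
color. Exploration proceeds in trials: a random pair of tables is offered,
the learner picks one, turns a card on one of its decks, and observes the
color. A round ends at a random time — lengths are `shift + G` with `G`
geometric at rate $1/44$ and `shift = 10`, so the test phase is equally
likely after any trial past the tenth and the mean round is 54 trials — and
is followed by a test in which the learner picks the richer deck on every
table and rates confidence on a 1–5 scale.

Beliefs are modelled with a conjugate Bayesian observer. Each deck carries a
flat $\mathrm{Beta}(1,1)$ prior over $\pi_i$; after $t$ cards with $c$
orange, the posterior is $\mathrm{Beta}(1+c,\,1+t-c)$ (sufficient counts are
all the observer stores — valid by conjugacy; raw card sequences stay in the
trial records). The posterior over $\theta$ follows by integration,

$$P(\theta = 1 \mid x) = \int_0^1 f_{\pi_1}(z)\, F_{\pi_2}(z)\, dz,$$

with $f$ and $F$ the Beta density and distribution function; the package
evaluates this with adaptive Gauss–Kronrod quadrature on $[0,1]$ at an
absolute tolerance of $10^{-8}$ (`stats::integrate`). Uncertainty is the
entropy of the two-point posterior,
$H(\theta \mid x) = -\sum_{\theta=\pm1} P \ln P$, in nats: 0 when the answer
is known, $\ln 2 \approx 0.69$ (one bit) when nothing is known. Three
trial-level decision variables derive from this machinery:

* **Expected information gain (EIG)** — the mutual information between
  $\theta$ and the next card: current entropy minus the
  predictive-probability-weighted entropy after an orange or blue draw.
  A table-level EIG needs a stance on which deck the next card would come
  from; the default takes the **maximum** over decks (an agent
  samples the deck it expects to learn most from), with mean and
  least-sampled alternatives available.
* **Uncertainty** — the entropy $H$ itself.
* **Exposure** — we use the *novelty* form of the exposure heuristic:
  $-n_x$, minus the number of cards already seen on the table, so that
  "choose the table with the least previous observations" predicts a
  positive slope on the right-minus-left difference. This sign convention
  matters: it is what makes the observed anti-correlation between choice
  and novelty an informative contradiction of the exposure hypothesis
  rather than a bookkeeping artifact.

All paired differences are right-minus-left; overall uncertainty
$U = H_\mathrm{left} + H_\mathrm{right} \in [0, 2\ln 2]$ measures decision
difficulty.

## The generative choice rule

A simulated agent chooses the right-hand table with probability

$$P(\text{right}) = (1-\varepsilon)\,\mathrm{logistic}\!\big(\beta_\mathrm{side}
+ \beta_\mathrm{rep} r + s(U)\, \Delta\big) + \varepsilon/2,$$

where $\Delta$ is the agent's strategy-specific decision-variable
difference on a calibrated scale, $r \in \{+1, -1, 0\}$ marks whether the
right or left table was chosen more recently (the *repeat option*; $r = 0$
before either table has been chosen), $\varepsilon$ is a lapse rate, and

$$s(U) = \begin{cases} \beta_\mathrm{dv} & U \le \tau\\
\beta_\mathrm{dv} + \beta_\mathrm{int}\,(U - \tau) & U > \tau \end{cases}$$

is the hinge-form threshold rule: below an overall-uncertainty threshold
$\tau$ the agent approaches uncertainty with slope $\beta_\mathrm{dv}$;
above it the slope changes by $\beta_\mathrm{int}$ per nat, and negative
values of $\beta_\mathrm{int}$ produce avoidance. We default to the
continuous hinge rather than a discrete slope switch because an interaction
of order $10^2$ is only dimensionally sensible if the moderator is a small
nats-scale excess over the threshold; the step variant ships behind
`form = "step"` since the printed record does not settle the
parameterization.

**Parameter defaults** (population draws in `agent_population()`):
$\beta_\mathrm{dv} \sim N(1, 0.25)$ per calibrated SD unit — matching the
order of the below-threshold slope seen in this paradigm;
$\beta_\mathrm{rep} \sim N(0.5, 0.2)$ — the documented size of the repeat
bias; $\beta_\mathrm{side} \sim N(0, 0.1)$; lapse $0.05$; no threshold
unless requested. The deck *sampled* on the chosen table defaults to the
least-observed one (`deck_policy = "least"`), reflecting the task
instruction that both decks must be sampled for the test to be solvable;
how real participants pick decks within a table is not constrained by the
choice analyses, so this remains a free simulation choice.

**Scaling.** Raw decision variables live on incommensurate scales (nats
versus counts). The generator divides each by a fixed calibration constant
— the SD of that variable in a large random-exploration simulation under
the default configuration (`eig` 0.0161 nats, `uncertainty` 0.273 nats,
`exposure` 3.99 cards) — and every simulated dataset stores these constants.
`prepare_predictors()` uses the stored constants by default, which makes
fitted slopes directly comparable to generating slopes (exact
generative–inferential symmetry); `scale = "zscore"` instead centers and
scales within dataset, the convention used when standardizing predictors
for regression. An online simulation cannot z-score against the dataset it
is still producing, which is why fixed calibration constants are the
generator's scale.

**The test phase** has no extra parameters: the simulated learner picks the
maximum-a-posteriori deck (random tie-break at $P = 0.5$). Because the
observer's posterior is calibrated under the generative card process, the
probability that this choice is correct equals the maximum posterior
probability, so accuracy falls to exactly chance as end-of-round entropy
approaches $\ln 2$, and confidence — the equal-width bin of the maximum
posterior on $[0.5, 1]$ into 1–5 — bottoms out for unsolvable tables
(a deck never sampled). Errors receive lower confidence automatically
because they concentrate where the maximum posterior is small; no separate
error-confidence parameter is introduced.

## Inference

**Strategy models.** For each candidate strategy we fit a logistic model of
the chose-right indicator on the side intercept, the repeat indicator and
that strategy's scaled difference. The reference analysis for this paradigm
uses Bayesian multilevel regression with standard-normal priors; we replace
it with its deterministic counterpart: ridge-penalized maximum likelihood
($0.5\lambda\sum\beta^2$ with $\lambda = 1$ on standardized predictors is
the MAP estimate under $N(0,1)$ priors), fit by damped Newton iterations.
The penalty also guarantees finite estimates under complete separation.
Individual differences are handled by a two-stage summary — per-participant
fits (at least 20 trials) pooled by inverse variance — rather than joint
random effects; the exact random-effects structure of the reference
analysis is not part of the printed record, and the two-stage design keeps
every estimate reproducible without posterior sampling.

**Model comparison** replaces importance-sampled leave-one-out with exact
participant-stratified 10-fold cross-validation: each model's score is the
summed held-out log predictive density, mirroring elpd semantics, with
pairwise-difference SEs over fold-level differences. Exact ties break
toward the simpler strategy (exposure < uncertainty < EIG). Folds whose
held-out responses are single-class are merged with a neighbor.
`recover_models()` wraps the loop simulate → fit → compare into the
generating-by-winning confusion matrix.

**The threshold model** profiles the ridge-penalized log-likelihood of the
four-parameter piecewise model over a grid of candidate thresholds
(default 0.30 to $2\ln 2$ nats at 0.005 resolution). The likelihood is not
smooth in $\tau$, so a grid profile is used instead of joint gradient
ascent; by default the search runs a coarse pass (every tenth grid point)
and refines around the optimum down to the grid resolution, which gives the
same optimum as the full sweep whenever the profile is unimodal — the
regime we observe throughout — at a tenth of the cost. The hinge regressor
$\max(0, U-\tau)\,\Delta u$ is standardized inside the fit so the penalty
acts on a unit-variance predictor, and the interaction is reported back in
per-nat units. Candidate thresholds with too few trials above them (under
1% of trials, minimum 20), or with less than 0.02 nats of headroom below
the observed maximum of $U$, are profiled without the interaction: in
those regions the hinge regressor has vanishing variance — $U$ is bounded
by $2\ln 2$, so near the ceiling the lever arm $U - \tau$ collapses — and
a back-transformed per-nat coefficient would be arbitrarily
ill-determined. If the profile optimum falls there, the interaction is
fixed at zero and flagged; for thresholdless data this leaves the profile
flat across the unidentifiable region, as it should be. Slope SEs are conditional on $\hat\tau$; the threshold's own
SE comes from the profile curvature at the optimum. An individual's
**avoidance score** is the triangular area above the declining segment of
the fitted effect line, $\tfrac12 |\beta_\mathrm{int}| (U_{\max} -
\hat\tau)^2$ for negative interactions (zero otherwise), with $U_{\max} =
2\ln 2$. Per-participant fits in `approach_avoid_individuals()` share the
group grid and add the group profile, weighted by the participant's share
of trials, as a log-prior — a light-touch shrinkage that stabilizes
individuals with few high-uncertainty trials.

## What the simulations do and do not show

The generator reproduces the structural statistics the analyses rely on:
shifted-geometric round lengths shared across participants in permuted
order, random pair presentation, grid-valued true proportions without
within-table ties (each deck's proportion is a tenth between 0.1 and 0.9,
resampled on ties — the tenths grid matches the ten open cards shown at
feedback; the original pseudo-random assignment scheme is not part of the
printed record, so the grid scheme is a configurable stand-in), practice
rounds that are simulated but excluded from analysis, repeat bias, lapses,
and threshold-dependent avoidance. It does not model reaction times,
forgetting (a lag-dependent lapse knob exists in concept but RT/lag
analyses are out of scope), within-round color semantics, or memory-limited
observers. Consequently, passing recovery tests demonstrates that the
estimation pipeline identifies the generating process under the stated
noise model — not that human data obey that model; coefficients estimated
from the deposited human dataset are outside this package's scope.

Two attenuation effects are worth knowing about when reading recovery
numbers. First, lapses flatten the choice curve, so fitting the lapse-free
logistic to lapsing agents shrinks slopes by roughly the lapse rate scaled
by the curve's steepness (about 9% at $\beta = 1$, $\varepsilon = 0.05$);
parameter-recovery checks therefore use lapse-free populations, while
ranking-based checks keep the default lapse. Second, the ridge prior
shrinks weakly-identified per-participant estimates; at hundreds of trials
per participant the bias is well under the reporting precision.

## Numerical choices and problem sizes

Quadrature: adaptive Gauss–Kronrod, absolute tolerance $10^{-8}$, results
clipped to $[0,1]$; entropies use the $0\ln 0 = 0$ convention; EIG is
clipped at zero against quadrature jitter (it is a mutual information).
Posterior probabilities for integer belief states are memoised up to 80
observed cards per table to keep long simulations fast without unbounded
memory. Newton fits damp by step-halving on the penalized likelihood and
declare convergence at a gradient norm of $10^{-10}$ (relative).

The shipped checks use these scales, chosen to give stable Monte-Carlo
margins on a single CPU: oracle sweeps of 300 (dense-grid) and 6
(10⁶-draw Monte-Carlo) hyperparameter tuples up to 25; model recovery with
20 replicates per generating strategy at 30 participants × 6 experimental
rounds with moderate slopes ($\beta_\mathrm{dv} = 1$); threshold recovery
with 20 replicates at the full study scale (194 participants × 18
experimental rounds, $\tau = 1$, $\beta_\mathrm{int} = -40$); and
test-phase validation over 10⁴ simulated rounds. The demonstration
pipeline (`make_demo_config()`) runs the entire stack at 30 × 6 in well
under a minute.

## Known limitations

* The hinge-versus-step form of the above-threshold term, and whether the
  threshold varies by participant, are design choices; both forms are
  implemented and the hinge is the default, with the group-grid shrinkage
  standing in for a hierarchical threshold.
* The two-stage population summary understates cross-participant shrinkage
  relative to a joint multilevel fit; comparisons and recoveries are
  insensitive to this, absolute population SEs slightly less so.
* EIG and uncertainty differences are strongly correlated by construction,
  so distinguishing them needs either many trials or clean (low-lapse)
  choices; the recovery matrix quantifies exactly this.
* The confidence model is intentionally minimal (a deterministic bin of the
  maximum posterior); only the qualitative shape of confidence curves is
  meaningful.
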