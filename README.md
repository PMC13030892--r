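# cardexplore

Simulation and model-based analysis of **uncertainty-guided exploration** in
an incremental learning task. The simulated environment is a room with four
tables, each holding two decks of cards; deck *i* hides a proportion
&pi;<sub>i</sub> of orange (vs. blue) cards, and the learner's goal on every
table is &theta; = sgn(&pi;<sub>1</sub> &minus; &pi;<sub>2</sub>) — which
deck is richer in the target color. On each exploration trial a random pair
of tables is offered; the learner picks one, flips a card on one of its
decks, and sees the color. Rounds end at a random, geometrically distributed
time and are followed by a test phase that rewards knowing &theta; for every
table. The scientific question the toolkit addresses: **which statistic of
prior learning drives the choice of what to explore, and when do learners
approach versus avoid uncertainty?**

The package is for computational cognitive scientists who want to simulate
this class of task, run the full inference pipeline on synthetic populations,
and verify — by parameter and model recovery — that the pipeline identifies
the generating process before pointing it at real data.

## The models

**Bayesian observer.** Each deck carries a flat Beta(1,1) prior; after *t*
cards with *c* orange the posterior is Beta(1+c, 1+t&minus;c). The posterior
probability that deck 1 is richer is

P(&theta;=1 | x) = &int;<sub>0</sub><sup>1</sup> f<sub>&pi;1</sub>(z) F<sub>&pi;2</sub>(z) dz,

computed by adaptive Gauss–Kronrod quadrature (abs. tol. 1e&minus;8).
Uncertainty is the entropy H(&theta;|x) = &minus;&Sigma; P ln P in nats
(0.69 nats = 1 bit for a fresh table). Three candidate decision variables
derive from the observer: **expected information gain** (the entropy
resolvable by the next card), **uncertainty** (H itself), and **exposure
novelty** (minus the number of cards already seen).

**Choice rule / piecewise threshold model.** Agents (and the fitted model)
choose the right-hand table with logistic probability driven by a side bias,
a repeat-option bias, and the scaled decision-variable difference &Delta;,
whose slope changes above a free overall-uncertainty threshold &tau;:

s(U) = &beta;<sub>low</sub> + &beta;<sub>int</sub> · max(0, U &minus; &tau;),  U = H<sub>left</sub> + H<sub>right</sub>

Negative &beta;<sub>int</sub> yields uncertainty *avoidance* when overall
uncertainty is high; the individual avoidance score is the triangular area
&frac12;|&beta;<sub>int</sub>|(U<sub>max</sub>&minus;&tau;)². Estimation is
ridge-penalized maximum likelihood (the deterministic analogue of
standard-normal coefficient priors) with the threshold profiled over a grid;
strategies are compared by participant-stratified 10-fold cross-validated
log predictive density.

## Worked example

```r
library(cardexplore)

# a table after 4 cards (3 orange) on deck 1 and 2 cards (0 orange) on deck 2
tb <- table_belief(deck_belief(4, 2), deck_belief(1, 3))
tb
#> Table belief: Beta(4, 2) / Beta(1, 3); P(theta = 1) = 0.9286, H = 0.2573 nats
expected_information_gain(tb)
#> [1] 0.0195
```

The observer is 93% sure deck 1 is richer, 0.26 nats of uncertainty remain,
and the next best-chosen card is expected to resolve about 0.02 nats.

The demonstration pipeline simulates 30 uncertainty-driven participants
(slope 1, repeat bias 0.5, lapse 5%, threshold &tau; = 1 nat with hinge
interaction &minus;40/nat), then fits and compares all three strategy
models, fits the threshold model, and validates the observer on the test
phase:

```r
report <- run_pipeline(make_demo_config())
report
#> Pipeline run report
#>   dataset: 30 participants, 16050 experimental trials
#>   winning strategy: uncertainty
#>   threshold tau = 1.000 nats, slope below = 0.885, change = -32.72/nat
#>   validation slope (accuracy ~ entropy) = -6.707
```

Reading those numbers: cross-validation correctly ranks the uncertainty
strategy above the EIG and exposure models (held-out log predictive
densities &minus;9430 vs. &minus;10246 and &minus;10344); the profiled
threshold lands on the planted 1.0 nats; the fitted slope change is
attenuated from &minus;40 toward &minus;33 by the agents' 5% lapse rate (see
the methods vignette); and test accuracy falls steeply with end-of-round
entropy — from near-perfect on resolved tables to chance at maximal
uncertainty. Each stage's tables and summaries are written under the
config's output directory (CSV/JSON/YAML only).

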