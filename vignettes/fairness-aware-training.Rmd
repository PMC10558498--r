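---
title: "Fairness-aware training for image-based diagnosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fairness-aware training for image-based diagnosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairdx)
```

## The problem

Deep classifiers used for computer-aided diagnosis can rank patients from
some demographic subgroups far less reliably than others, even when their
overall discrimination looks excellent. Because diagnostic scores are used
as *rankings* — who gets triaged first, who is flagged for chronic-disease
prevention — a fairness audit of such a model should be threshold-free and
rank-based rather than built on binarised error rates. `fairdx` implements
such an audit and a training procedure that reduces the disparity it
measures, together with a synthetic biased-cohort generator so that every
claim the package makes can be exercised end to end without access to
medical data.

## Metrics

**Pairwise Fairness** of subgroup $G_i$ is the marginal pairwise equal
opportunity criterion

$$\mathrm{PF}(G_i) \;=\; P\!\left(f(x) > f(x') \;\middle|\; y=1,\ (x,y)\in G_i,\ y'=0 \right),$$

the probability that a randomly chosen *positive of the subgroup* outscores
a randomly chosen *negative of the entire dataset*. It is the bipartite
ranking AUC of the subgroup's positives against the global negative pool.

Two consequences matter in practice:

* it is invariant to any strictly increasing transform of the scores and
  never consults a decision threshold (`pairwise_fairness()` property
  tests assert both);
* it is estimable by pair counting, so a brute-force $O(n^2)$ oracle can
  certify the rank-based $O(n\log n)$ implementation exactly. The test
  suite does this on random instances up to 300 samples.

**Tie handling.** The pairwise definition uses a strict inequality; ties
receive half credit here, so PF coincides with the Mann–Whitney AUC
(implemented with average ranks). Any other tie convention would break the
identity "PF of the whole set equals the overall AUC", which the package
treats as a defining consistency check.

**Negatives pool.** The conditioning event restricts the positive to the
subgroup but *not* the negative: the group's own negatives stay in the
pool. Excluding them would measure a different (within/between mixture)
quantity.

**PFD**, the pairwise fairness difference, is $\max_i \mathrm{PF}(G_i) -
\min_i \mathrm{PF}(G_i)$ over subgroups with at least one positive.
Subgroups without positives are excluded — PF is undefined there — rather
than scored as zero, which would inflate PFD arbitrarily.

**Relative change** between a baseline and a proposed value is
$(x_\mathrm{prop}-x_\mathrm{base})/x_\mathrm{base}$, reported as a percent
in comparison tables, and always recomputed from the stored means rather
than stored itself.

## The training procedure

The fairness-aware loss replaces (not supplements) binary cross-entropy.
Per minibatch:

1. score the batch and compute batch-level PF for every subgroup with at
   least one positive in the batch, against all batch negatives;
2. select the subgroup with the *lowest* batch PF (exact ties break
   lexicographically, making reruns deterministic);
3. minimise the marginal ranking loss of that subgroup's positives
   $x_p$ against the negative pool $x_n$:

$$\mathcal{L} \;=\; \frac{1}{n}\sum_{\text{pairs}} \max(0,\; -x_p + x_n + \mathit{margin}),$$

with $n$ the number of $(x_p, x_n)$ pairs. The hinge activates exactly on
pairs that are mis-ranked or ranked too closely, so a subgradient step
(the boundary $-x_p+x_n+\mathit{margin}=0$ takes subgradient 0) moves the
worst subgroup's positives up and the negatives down; one such step can
never decrease that subgroup's batch PF, a property the tests assert.

Design choices the procedure definition leaves open, and how this package
resolves them:

* **Reference pool at batch level.** The loss definition takes negatives
  from the whole training set, which is infeasible per step; the step uses
  all negatives of the current batch as the stochastic estimate. An
  optional FIFO buffer of recent negative predictions
  (`negative_buffer` in `train_config()`) can extend the pool; buffered
  entries enter the loss as constants and receive no gradient.
* **Margin.** Scores are positive-class probabilities (the two-logit
  softmax of a linear layer reduces to a single logistic unit, which is
  what `linear_scorer()` implements), so the margin lives on $[0,1]$. The
  default is 0.1: large enough to keep the hinge active beyond the first
  correct orderings, small relative to the score range. No published
  value exists for this constant; it is a package default, configurable.
* **Ineligible batches** (no positive anywhere, or no negative) skip the
  update entirely — the procedure replaces cross-entropy rather than
  mixing with it. Skips are counted per epoch in the training history and
  each applied step is logged (epoch, step, category, batch PF) for
  audit.

## Trainer and protocol

`train_scorer()` follows the standard protocol for this class of model:
Adam, learning rate $10^{-4}$, batch size 96, 20 epochs, random
rotations/flips for image payloads, and model selection by the highest
AUC on a development set. The published protocol describes 80/20
patient-level train/test splits but not the development set; this package
carves 10% of the *training patients* (patient-level, never the test
side) so that selection cannot leak test information.

The reference scorer is a linear logistic scorer with analytic gradients.
This keeps every training property verifiable at desk scale — seedwise
bitwise reproducibility, convergence of the cross-entropy mode to the
Gaussian closed-form AUC $\Phi(d/\sqrt2)$, loss-gradient finite-difference
checks — while the trainer accepts any scorer exposing the same
`forward`/`grad_params` interface. Deep convolutional backbones are out of
scope of the test suite by design.

Two baselines ship alongside the proposed mode: plain binary
cross-entropy (`bce`), and `oversample`, which equalises class counts by
resampling the minority *class* (not subgroup) with replacement before
cross-entropy training.

## The synthetic biased cohort

`generate_cohort()` emulates the three bias mechanisms that real
diagnostic cohorts exhibit:

* **prevalence imbalance** — disease rates differing several-fold between
  subgroups (e.g. 9.04% vs 2.58% across age groups in an ocular
  hypertension cohort);
* **sample-size imbalance** — subgroups of very different sizes at
  similar prevalence;
* **separability disparity** — the informative signal being weaker in
  some subgroups.

Labels are Bernoulli draws at *patient* level; each patient contributes
$1 + \mathrm{Poisson}(1)$ images that share the patient's group, label
and attributes, which is what makes patient-level splitting
consequential. Feature payloads have one informative dimension carrying a
mean shift of $d_g$ for positives in unit Gaussian noise (so the
Bayes-optimal scorer attains within-group AUC $\Phi(d_g/\sqrt2)$ —
parameter recovery tests assert this), eight pure-noise dimensions, and
one *group-marker* channel per group (value `marker_strength`, default
1, for members). The markers stand in for the group-correlated
appearance cues real medical images carry; they are what lets a linear
scorer learn group-dependent score offsets — the mechanism by which
prevalence imbalance biases a cross-entropy model *and* by which the
worst-group ranking loss can correct the bias. With
`marker_strength = 0` the payload carries no group information and no
linear scorer can treat groups differently.

The default benchmark (`paperlike_scenario()`) uses three race-like
groups with sizes proportional to 38,457 : 30,239 : 9,191 scaled by 1/20
(≈3,900 images, ≈1,950 patients), prevalences 0.70/0.40/0.37, and
separabilities 1.8/1.0/1.8 — the smallest group is also the hardest, so
both imbalance mechanisms act at once. The toy-image modality renders the
same signal as a centred disc plus a per-group corner marker on 32×32
rasters, exercising the imaging path.

What the generator does **not** emulate: realistic radiograph or fundus
texture, label noise, covariate shift between sites, correlated
attributes, or calibration structure. Passing tests on this benchmark
therefore demonstrate that the method behaves as designed under the
stated bias mechanisms — not that it will close fairness gaps on any
particular clinical dataset.

## The benchmark comparison

`run_experiment()` runs the full protocol: repeated patient-level 80/20
splits (5 repeats by default), each mode trained on the identical split
with the identical initialisation seed (a *paired* design, which removes
split-to-split variance from the comparison), fairness reports per
grouping on the held-out side, aggregation as mean ± sample standard
deviation (denominator $n-1$), and relative changes computed on the
means. `scripts/acceptance.R` reproduces the headline comparison —
percent PFD reduction and absolute AUC relative change between the
cross-entropy baseline and the proposed loss — from a single seed.

One behaviour of the desk-scale benchmark deserves a note. At the
protocol's budget (learning rate $10^{-4}$, 20 epochs) the linear scorer
is far from convergence, and the ranking loss — which optimises
pair orderings directly — tends to reach *higher* overall AUC than
cross-entropy at the same budget, so the AUC relative change between the
two modes is typically a small improvement rather than a small
degradation. Diagnostic runs at much longer budgets shrink this gap. The
acceptance script reports the measured value without adjustment.

The intersectional audit crosses the two groupings with the largest
baseline PFD (`intersectional_pick()`, lexicographic tie-break) and
re-evaluates the persisted per-repeat scores under the crossed
assignment — no retraining, so the intersectional numbers are exactly
commensurable with the individual ones.

## Subgroup bookkeeping

Numeric attributes bin into half-open intervals $[lo, hi)$ with the last
bin closed above, so a threshold of 75 places age 75 in the upper bin;
published cohort tables often print overlapping-looking labels
("65–75", "≥75") and this convention resolves them into a true
partition. Unknown or missing attribute values are an *error* naming the
offending samples — silently pooling them into an "Other" bin would
corrupt the very audit the package exists for. Race-style category
vocabularies differ between cohorts, so collapsing schemes are supplied
per dataset via `category_map`, never hard-coded. Cohort summaries round
half-up to two decimals, matching the convention of published
characteristics tables.

## Imaging chain

`preprocess_cxr()` min-max normalises to $[0,255]$, inverts when the
border (outer 10% frame) outshines the centre — the published
description of this step ("inverted, if necessary") names no predicate,
so the border-vs-centre mean heuristic is this package's
operationalisation — and applies *global* histogram equalization over
256 levels (the adaptive variant is another unstated choice; global was
chosen for determinism and idempotence). The chain is idempotent within
one intensity level on images with genuine centre/border contrast; on
contrast-free noise the inversion predicate sits at a tie and has no
stable fixed point, a documented boundary case. Augmentation draws a
rotation angle uniformly from $[0°,10°]$ with a random sign (the sign is
unstated in the protocol description), plus independent horizontal and
vertical coin-flip mirrors; rotation fills with black. Resizing is
bilinear to 224×224×3 by default (32×32 for the toy path), with
grayscale replicated across channels.

## Numerical and degenerate-input conventions

* Undefined metrics (no group positives, no global negatives, a
  single-class set, fewer than two eligible groups for PFD, a zero
  baseline for relative change) raise classed errors naming the
  quantity; they are never silently imputed.
* All category orderings are lexicographic in the C locale, which fixes
  every downstream tie-break (worst-group selection, intersectional
  pick) across platforms.
* All randomness — generation, splitting, initialisation, data order,
  oversampling, augmentation — flows from integer seeds through one
  derivation function, so every pipeline stage is independently
  reproducible and derived seeds stay within 32-bit range.
* Problem sizes in the shipped tests and benchmark (≈3,900-image
  cohorts, 5 repeats, 2,000-sample parameter-recovery checks) were
  chosen so the full suite completes in well under a minute while
  keeping Monte-Carlo error small relative to every asserted tolerance.

## Known limitations

* The reference scorer is linear; it can reweight features and apply
  group offsets but cannot learn interactions. The bias-reduction
  mechanism it demonstrates (equalising group score offsets) is the
  linear shadow of what a deep backbone would do with group-correlated
  image content.
* Probability calibration is out of scope: the metrics are rank-based
  throughout, and nothing is claimed about calibrated risk.
* Binary labels and discrete attributes only; continuous protected
  attributes and multi-class endpoints are not supported.
* The oversampling baseline equalises classes, not subgroups.
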