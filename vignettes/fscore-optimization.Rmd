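---
title: "Cost-sensitive Fβ optimization: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive Fβ optimization: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fola)
```

## The model and its assumptions

The package targets binary and multi-label classification where the metric
of record is the Fβ score and the classes are heavily imbalanced. The
training objective is the class-weighted binary cross-entropy

$$\ell(x, y) = -w\,[\,y \log x + (1-y)\log(1-x)\,],$$

with $w = w_{pos}$ on positive elements and $w_{neg} = 1$ on negative
ones; only the ratio of the two matters. Writing the score in count form,

$$F_\beta = \frac{(1+\beta^2)\,TP}{(1+\beta^2)\,TP + \beta^2 FN + FP},$$

eliminating $TP = N_{pos} - FN$ and differentiating with respect to $FN$
and $FP$ gives the relative cost of a missed positive versus a false
alarm. That ratio is the Fβ-optimal positive-class weight:

$$w_{pos} = \frac{1}{Pr} + \frac{\beta^2}{Rc} - 1,$$

evaluated at the precision and recall of the optimal model. Two structural
assumptions follow from this derivation and shape the whole package:

* **Fixed operating point.** Predictions are positive when the predicted
  probability is at least 0.5 — inclusive, never tuned. A well-weighted
  model should perform at the predetermined threshold; the weight, not the
  threshold, carries the cost information. For $\beta = 1$ the two views
  coincide through the identity $1/(1 + w_{pos}) = F_1(Pr, Rc)/2$: the
  cost-sensitive Bayes rule at the optimal weight thresholds the posterior
  at half the optimal F1, the classical plug-in characterization. The
  package asserts this identity to $10^{-12}$ and verifies the derivative
  ratio against central finite differences.
* **Validation-driven estimation.** The optimal $Pr$ and $Rc$ are unknown
  before training, so the trainer estimates them epoch by epoch on the
  validation split (training-set metrics would be optimistic and
  underestimate the weight) and re-derives $w_{pos}$ after every epoch.
  Test data never participates in a weight update: test-set evaluation
  uses `fixed_weight_train()` with the weight frozen at its final
  validation estimate.

The binary formulation does not extend to multi-class F-scores (with no
designated positive class the score loses its meaning), and the package
does not attempt it.

## The training algorithm

`fola_train()` implements the per-epoch loop: build the weighted BCE with
the current weight(s), train one epoch, evaluate validation precision and
recall at 0.5, update the weight(s). Degenerate updates (a label with zero
validation true positives, which forces $Pr = 0$) revert to the
user-supplied initial weight — the single fallback trigger. The update
happens exactly once per epoch, after validation, never intra-epoch.

Key parameters, defaults and rationale:

| Parameter | Default | Why |
|---|---|---|
| `beta` | 1 | F1, the common choice; any positive β is accepted. |
| `initial_wpos` | `"upper_bound"` | $N_{neg}/N_{pos}$ equalizes class mass and brackets the optimum from above ($w^\ast \in [1, N_{neg}/N_{pos}]$); a poor start matters little because validation estimates take over from epoch 2. |
| `bounding_factor` | 2 (macro), none (micro) | Macro-mode per-label weights are capped at twice their median; micro mode has a single weight and is instead safety-capped at $N_{neg}/N_{pos}$, beyond which the update has no rational interpretation (a warning is logged). |
| `threshold` | 0.5, fixed | See above; not a tunable. |
| `lr_schedule` | triangular cyclical, base = 5% of peak, one cycle per run | Starts low, so early epochs under a possibly poor initial weight take small steps; for schedules that start high a linear warmup of two epochs is enforced by default. |
| `refine_passes`, `refine_tol` | 3, 0.02 | Optional multi-pass refinement: retrain from scratch with the previous pass's final weight frozen; declare convergence when the relative weight change falls below the tolerance. An infinite tolerance accepts the first pass. |

The reference learner is a per-label linear-sigmoid (logistic) model
trained by mini-batch gradient descent. It is deliberately minimal: convex
per label, fast enough that every optimality claim can be tested against
brute-force oracles, and well-specified on the package's Gaussian tasks so
that calibration arguments apply. Deep models plug in through the
two-generic learner interface (`predict_proba()`, `train_one_epoch()`).

### The soft-Fβ baseline

The comparison baseline replaces hard counts with probabilistic ones
($TP = \sum O\,T$, $FP = \sum O\,(1-T)$, $FN = \sum (1-O)\,T$) and
minimizes the negated score of the current batch. Batch-local counts make
its gradients noisy in rare-positive regimes, and a batch with no positive
mass has an undefined score; the package defines that degenerate case as
zero loss with zero gradient — the minimal intervention. When predictions
are binary the soft counts equal the hard counts exactly, which the tests
assert.

## Synthetic tasks: what they emulate and what they do not

All empirical claims are checked on generated tasks with *known*
posteriors, because optimality statements need a ground truth no scraped
dataset provides.

* `make_binary_gaussian_task()`: Bernoulli labels, isotropic Gaussian
  class-conditional features a configurable distance apart; the posterior
  is exactly logistic in the linear discriminant. The reference task used
  throughout the acceptance suite has $n = 50{,}000$, prior 0.02 and
  separation 2 — a 49:1 imbalance with a best achievable F1 around 0.40
  (computed by the package's own fixed-point and threshold-sweep oracles).
* `make_multilabel_task()`: labels driven by shared latent factors
  ($z \sim N(0, I)$, label $l$ positive with probability
  $\sigma(a_l \cdot z + b_l)$), intercepts solved so marginal rates follow
  a rank-frequency power law (by default scaled so the top 16 labels hold
  about half the positive mass, and the rarest label reaches the
  configured negative:positive ratio). Features observe the factors
  through a linear map plus Gaussian noise. A factor absent from the map
  is invisible; a label tied to it is predictable only through co-occurring
  visible factors — the analogue of inferring a hidden ingredient from the
  visible ones it accompanies. Because the conditional $z\,|\,x$ is
  Gaussian, the marginal posteriors $p(y_l\!=\!1\,|\,x)$ are exact
  one-dimensional Gaussian expectations of a logistic, computed by 41-node
  Gauss–Hermite quadrature (machine-precision for these scales); the tests
  verify binned calibration.

What the generators deliberately do **not** emulate: image feature
extraction, non-linear decision boundaries, label noise, covariate shift
between splits, or the optimizer pathologies of deep networks. Passing
tests therefore demonstrate the correctness and optimality of the
weighting rule under clean, well-specified conditions — not that a
particular deep backbone will realize those gains on real images.

## Numerical choices

* Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before logarithms.
* The loss reduces by the mean over all $n \times L$ elements; this
  couples the weight scale to the learning rate and is stated explicitly
  because per-label summing would change effective step sizes.
* Confusion counts are exact integers; metric arithmetic is double
  precision. Per-label Fβ is 0 whenever $TP = 0$ (an unpredictable label
  scores zero even though its precision is undefined); an option excludes
  labels with no positive instances from the macro average but defaults
  off. The IoU of two empty sets is 1. IoU and cardinality statistics are
  computed wherever prediction sets exist, on any split.
* The median used in weight bounding is the standard midpoint-of-central-
  order-statistics convention for even lengths, recomputed at every update
  from the current pre-bounding vector over *all* labels (including ones
  that fell back), keeping the cap adaptive.
* The threshold sweep in `brute_force_threshold_f1()` only cuts between
  strictly distinct scores (inclusive thresholding cannot split ties) and
  always evaluates the all-positive and empty rules; it accepts soft
  labels, which turns it into an expected-score sweep on a posterior.
* The learner-free fixed-point iteration of the weight update damps
  sign-alternating oscillations by averaging the two most recent iterates;
  plain iteration is used otherwise.
* The one-tailed Welch test uses Satterthwaite degrees of freedom; two
  zero-variance samples resolve by the sign of the mean difference.

## Problem sizes

The test and acceptance suites run at sizes chosen to make sampling error
negligible relative to the asserted margins while keeping a full run in
the low minutes on one CPU: the reference binary task at $n = 50{,}000$
(calibration checks at $10^5$), the loss-function ablation with five grid
weights and three seeds at 20 epochs, and the macro study on a 50-label
task ($n = 12{,}000$, priors spanning 100:1 geometrically from 0.35 to
0.0035, eight latent factors, 12 epochs, three seeds).

## Known limitations and an honest negative result

* **Macro-mode weight bounding does not help the reference learner.** The
  motivation for capping per-label weights is overshoot: extreme weights
  produce disproportionately large gradient steps that degrade a *shared*
  representation. The package's reference learner has no shared
  parameters — each label's problem is convex and independent — and since
  $w_{pos} \le N_{neg}/N_{pos}$ the total positive weight mass per label
  never exceeds the negative mass, so the weighted-loss curvature is never
  inflated and overshoot cannot engage. On the 50-label study the test
  suite measures the consequence: the unbounded variant *outperforms* the
  bounded one (large weights are the only way rare, hard labels ever cross
  the 0.5 threshold and score above zero), and the corresponding
  acceptance assertion fails by about 0.04 macro F1. A probe with the
  minimal shared-representation analogue (a rank-8 shared linear
  bottleneck) reproduced the same ordering. The bounding machinery is
  implemented, tested for its mechanics (cap, median convention,
  idempotence) and available for learners that do share parameters, where
  the overshoot mechanism is expected to bind.
* Dynamic weighting's advantage over the soft-Fβ loss on the reference
  task is real but modest (the batch-local count noise that penalizes the
  soft loss at scale is milder for a convex learner); the Welch test still
  separates them at the 5% level over three seeds.
* The package trains by plain mini-batch gradient descent; adaptive
  optimizers, dropout and augmentation are out of scope for the reference
  learner and belong to user-supplied learners.
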