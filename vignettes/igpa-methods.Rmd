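---
title: "Information-gain proportioned averaging: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-gain proportioned averaging: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(igpa)
```

## The problem

A bank of image classifiers — here, fine-tuned CNN heads over several
pre-trained backbones, applied to seven-class dermoscopic skin-lesion
images — produces one class-probability matrix each. The question is how
to fuse them. Plain averaging treats a 95%-accurate model and an
80%-accurate one identically; stacking a meta-learner needs extra
training. Information-gain proportioned averaging (IGPA) sits between
the two: it derives a weight for each classifier from how much its
*correctness indicator* reduces uncertainty, then fuses by weighted
averaging. No parameters are learned.

## The weighting rule

For classifier $i$, evaluated on a weighting label set of $n$ samples:

1. **Correctness.** Each sample gets a bit $x_j \in \{0,1\}$: 1 when the
   classifier's maximum-probability class equals the true label. The
   empirical accuracy is $a_i = \tfrac1n \sum_j x_j$.
2. **Entropy.** The correctness bit is a two-outcome variable, so its
   entropy is the binary entropy
   $H(a_i) = -a_i \log_2 a_i - (1-a_i)\log_2(1-a_i)$, in bits.
3. **Information gain.** With reference entropy $h_{\mathrm{prior}}$
   (default 1 bit, the no-information state of a binary variable) and
   level parameter $\alpha$,
   $\mathrm{IG}_i = \alpha\,\max\!\big(0,\; h_{\mathrm{prior}} - H(a_i)\big).$
4. **Weights.** $w_i = \mathrm{IG}_i / \sum_k \mathrm{IG}_k$.
5. **Fusion.** $E_{jc} = \sum_i w_i\, p_{ijc}$ per sample $j$ and class
   $c$ — a convex combination, so row-stochastic inputs give a
   row-stochastic output.

```{r}
sim <- simulate_predictions(simulator_config(
  n_samples = 2000, classifier_accuracies = c(0.95, 0.85, 0.70), seed = 42))
fit <- igpa_ensemble(sim$preds, sim$truth)
round(fit$weights, 4)
```

An IG of 0 happens exactly at coin-flip correctness ($a_i = 0.5$); a
perfectly accurate classifier reaches the maximum, $\alpha \cdot
h_{\mathrm{prior}}$. On $(0.5, 1]$ the gain is strictly increasing in
accuracy, so the weight ordering always reproduces the accuracy
ordering there. Two edge cases are handled explicitly rather than
silently:

* **Accuracy below 0.5.** The entropy gap is symmetric about 0.5, so a
  10%-accurate classifier would score like a 90%-accurate one. We do not
  clamp or re-map; we raise a warning, because a sub-coin-flip
  classifier in this pipeline indicates a broken input rather than a
  weighting subtlety.
* **All gains zero.** The ratio in step 4 is undefined; the uniform
  vector is returned with a warning.

Argmax ties in step 1 go to the lowest class index, deterministically,
so repeated runs agree bit for bit.

### The role of $\alpha$, and why there are two modes

$\alpha$ is the level of the ensemble (below). Entering
*multiplicatively*, as defined above, it cancels in the normalization of
step 4: weights are identical for every $\alpha > 0$. The package's
default mode is this faithful multiplicative form — the arithmetic is
exactly the defining chain, and the cancellation is itself a tested
invariant. Because the stated *intent* of $\alpha$ is to let stronger
models dominate more as levels stack, an opt-in `mode = "exponent"`
computes $\mathrm{IG}_i = (h_{\mathrm{prior}} - H(a_i))^{\alpha}$
instead. Since the entropy gap lies in $[0, 1]$, raising it to a power
$\alpha \ge 1$ *spreads* the gains apart: the best-to-worst weight ratio
is non-decreasing in $\alpha$. Every report records which mode produced
its weights.

### Which labels feed the weighting?

The correctness bits must be computed against *some* label set. Scoring
them on the same partition used to report performance lets the ensemble
adapt to its own test set — a leak. The package therefore keeps the
weighting set a caller-supplied input everywhere (`weighting_preds` in
`igpa_ensemble()`, `weighting_store` in `run_tree()`), with held-out
validation predictions as the recommended choice, and the command-line
interface refuses to reuse one file for both weighting and evaluation
unless `--allow-leak` is passed.

## Multi-level IGPA

At a single level over many classifiers, individual weights are small
and a genuinely superior model cannot dominate. The multi-level variant
(ML-IGPA) fuses level by level over a tree. The reference topology
(`ml_igpa_topology()`) mirrors a 36-classifier dermoscopy ensemble:

* **Level 1** — nine nodes, one per backbone (DN121, DN169, DN201,
  MNv1, MNv2, MNv3L, Iv3, IRv2, X), each fusing that backbone's four
  attention heads (CCNN, CACNN, SEACNN, SACNN) at $\alpha = 1$;
* **Level 2** — three family nodes: DN (the DenseNets), MN (the
  MobileNets), IX (Inception/Xception), at $\alpha = 2$;
* **Level 3** — the DMIX root over DN, MN, IX at $\alpha = 3$.

The `"best3"` variant applies top-3 selection (by weighting-set
accuracy, ties by lexicographically smaller source id) uniformly at
every node; it only bites at level 1, where nodes have four children.
Leaves sit at level 0 and `alpha` defaults to the node's level. One
naming note: the level-1 MobileNet backbone node is `MNv1`, not `MN`,
because `MN` names the level-2 family node and node ids must be unique
within a tree.

```{r}
root <- ml_igpa_topology("best3")
root
```

`run_tree()` traverses post-order, keeps the full per-node accounting
(accuracies, gains, weights) in an `ensemble_report`, and propagates a
*second* stream of weighting-set predictions through the tree so that
level-2 and level-3 weights can also be computed leak-free from held-out
data.

## Baselines

Three conventional fusion rules are included for ablation comparisons,
all sharing the same ranking label set as IGPA for comparability:

* **Softmax averaging** (`softmax_average()`): the unweighted mean;
  algebraically identical to IGPA when all classifiers have equal
  empirical accuracy.
* **Majority voting** (`majority_vote()`): modal argmax class. The vote
  tie rule is not standard anywhere, so we fix one: largest summed
  probability over the tied classes, then lowest class index.
* **Fixed-weight averaging** (`fixed_weight_average()`): rank by
  accuracy, then assign a preset profile — 30/26/24/20% over four
  classifiers (`"wa4"`) or 35/35/30% over three (`"wa3"`). Arbitrary
  profiles are accepted too.

## Evaluation metrics

`classification_report()` computes the one-vs-rest decomposition per
class and aggregates precision, recall and F1 by **support-weighted**
averaging. That choice is deliberate: support-weighted recall is
algebraically identical to accuracy (each diagonal cell is counted once,
weighted by its row share), which is why recall equals accuracy in every
results table this style of analysis produces — a property the test
suite asserts on random confusion matrices. Specificity is aggregated by
**unweighted (macro)** averaging: with a dominant class near 67% of
samples, weighted specificity would be pinned near that class's value,
whereas macro specificity sits visibly below accuracy, matching how the
quantity is conventionally reported for imbalanced dermoscopy data.
Per-class metrics with a zero denominator are reported as 0 with a
warning rather than dropped, so aggregate values remain defined.
Percentages print rounded half-even to two decimals.

ROC-AUC is one-vs-rest per class via the threshold/trapezoid
construction with tie groups collapsed, which makes it equal to the
pairwise ranking probability $P(s_{\mathrm{pos}} > s_{\mathrm{neg}}) +
\tfrac12 P(=)$ — the brute-force pairwise estimator is the test oracle,
and pROC serves as an additional independent cross-check. Classes
without both a positive and a negative sample get `NA` and are excluded
from the macro mean.

## Attention operators

The three attention blocks used by the classifier heads are provided as
inference-only forward passes on explicit weight matrices (no training
machinery):

* **Channel attention**: per-channel descriptor (spatial mean,
  optionally concatenated with the population standard deviation —
  population, so a $1\times1$ plane yields 0 rather than `NA`), then
  gates $w_c = \sigma(W_2\,\mathrm{ReLU}(W_1 d))$ applied per channel.
  Gates lie in $(0,1)$, so the operator never amplifies — a property
  test. The descriptor choice is configurable (`"mean_std"` default,
  honoring the mean-and-standard-deviation description) because the
  exact descriptor of the original layer is unstated; the hidden width
  defaults to $\max(1, \lfloor C/8 \rfloor)$.
* **Squeeze-and-excitation**: squeeze to channel means, excite via
  $s = \mathrm{ReLU}(W_2\,\mathrm{sigmoid}(W_1 z))$. This activation
  order (outer ReLU, inner sigmoid) inverts the usual
  squeeze-excitation design; it is implemented exactly as specified,
  and documented as such — the gates are non-negative but unbounded
  above.
* **Soft attention**: a shift-stabilized softmax over scalar scores;
  invariant to adding a constant to every score.

## The synthetic generator, and what it does not emulate

Real classifier outputs for this problem would require training 36 CNNs
on ~10,000 dermoscopic images. The generator replaces them with a
controlled statistical stand-in:

* labels drawn from a nevus-dominated 7-class prior (NV ≈ 67%,
  qualitatively matching the HAM10000 imbalance, not its exact counts);
* per classifier and sample, a correct/incorrect Bernoulli draw at the
  classifier's target accuracy, mixed with a shared per-sample
  difficulty draw with probability `correlation` (default 0.3), so
  mistakes cluster on common hard samples;
* a probability row concentrated on the predicted class via
  Dirichlet-style gamma draws (`concentration` default 10, giving
  typical top probabilities around 0.8 for seven classes), with the
  predicted class guaranteed to be the row's argmax — so each
  classifier's empirical accuracy is exactly a binomial draw at its
  target rate, which is what makes the 3-sigma recovery test a clean
  statement;
* wrong classes uniform over the remaining six by default, with an
  optional confusion-bias matrix for harder fixtures;
* default accuracies spread over 0.85–0.95, the range spanned by the
  individual fine-tuned classifiers this setup emulates.

The default parameters are fixed study conditions, not tuning knobs.

What the generator does **not** reproduce: the strong error correlation
of real CNNs trained on the same data. With weakly correlated mistakes,
fusing many classifiers removes almost all errors — simulated ensembles
here saturate near 100% accuracy, well above anything achievable on real
dermoscopy data. Passing tests therefore validate the *arithmetic and
invariants* of the method (weight normalization, dominance ordering,
level-wise composition, leak-free splitting), not its clinical
performance; the published-scale accuracy figures of the original
experiments are not reproducible without GPU-trained classifiers and
are out of scope here.

Grouped splitting emulates lesion-id structure: `make_manifest()`
assigns each lesion one class and possibly several images;
`grouped_split()` shuffles lesions by seed and fills test, then
validation, to their image-count quotas, remainder to train. Whole
lesions move together, so no lesion ever spans partitions; sizes are
exact whenever lesions are unique and the fractions divide the image
count (the 70/15/15 default on 1,000 unique lesions gives exactly
700/150/150). With multi-image lesions the quota-filling is greedy and
sizes can overshoot by at most one lesion — documented, not hidden.

## Numerical choices and degenerate inputs

* Entropy is in bits (log base 2), matching the two-event framing;
  $0\log_2 0 := 0$.
* Row-stochasticity is validated at `1e-6` on input; weight vectors at
  `1e-9`; the softmax uses a max shift to avoid overflow.
* CSV serialization uses 9 significant digits (round-trips are faithful
  to ~1e-9 relative error); class order is fixed by the header; sample
  alignment is by row order.
* All tie-breaks (argmax, vote, ranking) are documented above and
  deterministic; every stochastic entry point takes an explicit seed.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on simulated
inputs at sizes chosen to make the statistical assertions sharp but the
runs quick on a single CPU: n = 5,000 for accuracy-recovery checks
(3-sigma binomial width ±1.7% at accuracy 0.9), n = 2,000 for weight
dominance and the 36-classifier tree, 1,000 randomized splits for the
leakage sweep, and up to n = 200 with ≤ 10 classifiers for the
brute-force oracle comparisons.

## Known limitations

* The multiplicative $\alpha$ makes ML-IGPA's level parameter inert in
  the default mode; the exponent mode is the mechanism that actually
  amplifies dominance with depth. Both are first-class and recorded in
  reports.
* Weighting on accuracies below 0.5 is warned about, not corrected;
  IGPA is not a boosting rule.
* No meta-learner stacking, no probability calibration, and no
  training of the attention blocks — the operators are forward passes
  for inspection and testing.
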