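---
title: "Methods: detector evaluation and voting ensembles for camera-trap imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector evaluation and voting ensembles for camera-trap imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A long-running Eurasian lynx survey produces a dataset with two defining
features: scale (hundreds of thousands of triggered images) and extreme
class imbalance (positive prevalence around 0.55%). Generic ImageNet
classifiers can be repurposed as binary detectors at zero training cost:
run each image through a model, keep the five highest-probability classes,
and declare a detection when a target synset appears among them. The
questions the package answers are (a) how good each pre-trained model is
as such a detector, measured with statistics that survive heavy imbalance,
and (b) how much a simple voting ensemble of the best models improves on
any single one.

## Detection mapping

ImageNet has no "lynx" class proper; two synsets cover the animal,
`n02127052` (*lynx, catamount*) and `n02125311` (*cougar, puma, catamount,
...*). Because the label word *catamount* appears in both, matching is done
on synset ids only — label strings are display metadata. An image/model
cell is positive iff the intersection of the model's top-5 ids with the
target set is non-empty; rank and confidence within the top-5 are
deliberately ignored (no confidence threshold is applied — membership alone
decides). Two invariants follow and are tested as properties: detections
are invariant to rank permutations and confidence perturbations, and
enlarging the target set can only switch cells from FALSE to TRUE.

Groups with fewer than five ranks are accepted; detection uses whatever is
present. Images that carry a truth label but no predictions count as "not
detected" rather than erroring, mirroring a model that failed to emit
output; the reverse situation (predictions without truth) is a hard
validation error because it would silently corrupt the confusion counts.

## The metric suite

All twelve parameters are closed-form functions of TP/TN/FP/FN, computed
in double precision from the raw counts (never from previously rounded
rates). Accuracy is reported but is nearly meaningless at 0.55% prevalence
— the all-negative detector scores ACC = 0.9945 — which is why the suite
centres on the imbalance-robust statistics: balanced accuracy, geometric
mean, Youden's index, discriminant power, F1, MCC and Cohen's kappa.

Numerical choices worth recording:

* **Kappa** uses the closed count form
  2(TP·TN−FP·FN)/[(TP+FP)(FP+TN)+(TP+FN)(FN+TN)], algebraically identical
  to (p~o~−p~e~)/(1−p~e~) but with no intermediate rounding; the test suite
  checks both forms agree to 1e-12 on 1000 random count vectors. Counts
  are held as doubles throughout: the cross-products overflow 32-bit
  integers already at this dataset's size.
* **Discriminant power** is the scaled sum of the base-10 logits of TPR
  and TNR. Two conventions circulate (natural vs base-10 logarithms); the
  base-10 form is the one consistent with the reference tables. Moreover,
  the reference analysis evidently evaluated the scale factor √3/π with π
  rounded to 3.14: all 39 published DP values match scale √3/3.14 to
  <5e-7, while the exact constant leaves a uniform 0.05% relative residual.
  `compute_metrics()` therefore defaults to `dp_scale = sqrt(3)/3.14` and
  exposes the exact constant as an argument. This was established from the
  printed-value evidence, not fitted.
* **Undefined metrics.** Degenerate detectors are legitimate inputs (a
  model that never fires has TP+FP = 0), so a zero denominator flags the
  affected field as `NA` with a warning instead of raising, and the rest
  of the row is still computed. DP is undefined whenever TPR or TNR is
  exactly 0 or 1.
* **Display rounding.** Reports round rate-like metrics to 5 decimals and
  GM/YI/DP to 6, matching the reference presentation; stored values remain
  full precision.
* **Ranking ties** break by the metric, then MCC, then lexicographic model
  id, so top-/bottom-k reports are deterministic.

One reproduction caveat: the published TPR/TNR pair of one model
(`Mob_v3_smlm`) is a truncation, not a rounding, of the values implied by
its own confusion counts; the package reproduces the counts' arithmetic
and the corresponding acceptance expectation documents the two-cell
discrepancy rather than absorbing it into a wider tolerance.

## Ensemble construction

Member selection ranks models by kappa and applies, in order: a hard
cutoff (κ ≥ 0.2, the conventional "fair agreement" floor — on the
reference table ten models pass, although the source prose counts eight),
an optional truncation before the first adjacent relative κ drop larger
than `drop_fraction` (the reference's 28.7% drop between ranks 4 and 5),
and a cap at `max_members`. Keeping the drop rule an explicit parameter
rather than hard-coding "top 5" separates the two criteria the reference
conflates.

A Multi-k ensemble with threshold t detects an image iff at least t of its
k members do; t = 3 is the default for k in 3..5, and `threshold_search()`
evaluates every t in 1..k by brute force. The objective the reference
optimized is unnamed; kappa is used by default, consistent with the metric
that drives member selection, and the choice is a parameter, not an
assertion about the source's intent. Threshold monotonicity (TP and FP
non-increasing in t, TN and FN non-decreasing) is asserted as a property
on random matrices.

Relative improvement of an ensemble over a standalone model is reported as
100·(e−s)/e, i.e. with the *ensemble* value in the denominator — the only
convention that reproduces all three published comparisons (23% F1, 23.5%
κ, 22.5% MCC) simultaneously.

## Synthetic data: what it emulates, what it does not

The generator's world restates the reference study: 293,604 images,
prevalence 1630/293,604, and the 36 observed (TPR, TNR) profiles. Since
the source reports nothing about inter-model correlation (all models saw
the same images, so detections must correlate positively), correlation is
exposed as a latent Gaussian parameter ρ with default 0.5 — a deliberate
midpoint, not an estimate — and the suite never relies on its specific
value beyond monotonicity.

Mechanics: each image carries a latent difficulty z ~ N(0,1); model m
detects image i iff ρ·z~i~ + √(1−ρ²)·ε~im~ ≤ Φ⁻¹(p~m~), with p~m~ equal to
the model's TPR on positives and 1−TNR on negatives. Because the latent
variable is standard normal for every ρ, marginal rates are exact by
construction (a Gaussian copula), which the calibration tests verify at 3
binomial standard errors. Detected cells place one target synset at a
uniform rank among five; remaining ranks are distinct distractors from a
30-synset pool of plausible wildlife confusions; confidences are sorted
uniform draws — their magnitudes are never used downstream, only top-5
membership. Positives are Bernoulli(prevalence) per image, with
`fixed_positive_count` available to pin exactly 1630.

What a green test does *not* establish: the generator has no notion of
image quality, camera site, temporal autocorrelation, or the full
1000-class confusion structure — it reproduces the binary detection layer
only. Pipeline tests therefore validate plumbing and statistics, not
classifier behaviour on real imagery. Tests and the acceptance run use
scaled-down n (400–50,000) to stay within time budgets; the generator's
defaults themselves stay at the study's stated size. The parameter-recovery
check runs at n = 50,000 with prevalence raised to ~5.5% so the positive
class is large enough for 3-SE bounds to be meaningful at that n.

## Storage

Records and truth persist as CSV, JSONL, or a three-table SQLite store
(`predictions`, `truth`, `models`) with a composite primary key on
(image_id, model_id, rank). R-side SQLite bindings are not assumed: the
fixed-schema store is driven through the Python standard library's
`sqlite3` via short generated scripts, exchanging CSV. Round-trips are
exact for ids and ranks and well below 1e-12 for confidences. The CLI
config file is JSON (a YAML reader is not a dependency of this package).

## Known limitations

* The ensemble layer implements unweighted threshold voting only; weighted
  or stacked combiners are out of scope by design.
* ROC/PR analysis is absent because the detection rule is thresholdless
  (top-5 membership), so each model yields a single operating point.
* The SQLite bridge requires a `python` executable on PATH; CSV/JSONL
  paths have no such dependency.
* `detect_one()` trusts its target set; it does not consult the model
  catalog to verify the synsets exist in the model's label space.
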