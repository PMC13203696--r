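---
title: "Selecting prediction pipelines for incomplete clinical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting prediction pipelines for incomplete clinical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical tabular datasets are pervasively incomplete — labs go unordered,
vitals are intermittently recorded, outcome labels are scarce — and the
best prediction pipeline (which imputer, which classifier, or an
end-to-end missingness-aware model) depends strongly on the dataset's
missingness profile.  Choosing a pipeline for a new dataset by exhaustive
benchmarking is expensive; choosing a fixed default leaves performance on
the table whenever the data conditions shift.

`misselect` treats this as an algorithm selection problem.  A dataset is
summarized by a cheap *static missingness fingerprint*; a library of
previously characterized datasets (a *knowledge base*) maps fingerprints
to per-method performance; and a weighted k-nearest-neighbour vote
recommends which pipeline to deploy.  Because clinical groups rarely have
enough datasets for nearest-neighbour methods to work, the toolkit expands
a small library by *constructive instance augmentation* — controlled
quality perturbations (MCAR and MNAR missingness injection, label
trimming) that turn each base dataset into several distinct
meta-instances — and sharpens the distance metric by *dynamic-supervised
metric learning*, which tunes the fingerprint weights so that static
distances mimic the similarity of full performance sweeps.

## The missingness fingerprint

Ten structural dimensions, each in $[0,1]$, computed from the data matrix
and labels alone:

| dim | meaning | definition |
|-----|---------|------------|
| f1  | global missing rate | mean of the missingness mask |
| f2  | label rate | fraction of rows with a 0/1 label (sentinel $-1$ marks unlabeled rows) |
| f3  | missing-rate heterogeneity | population variance of per-feature missing rates, divided by $0.25$ (the maximal Bernoulli variance, at $p = 0.5$) |
| f4  | max feature missingness | largest per-feature missing rate |
| f5, f6 | mask structure | mean and max absolute Pearson correlation between mask columns |
| f7  | missingness–label link | absolute correlation between per-row missing count and the label |
| f8  | class balance | minority/majority count ratio |
| f9  | pattern diversity | unique missingness patterns / $N$ |
| f10 | pattern concentration | most frequent pattern / $N$ |

An eleventh dimension, $f_{11} = -\log_{10}(\max(p, 10^{-300}))$ of
Little's MCAR test, is stored with every knowledge-base instance as a
mechanism indicator but **never enters any distance computation** — the
recommender works from f1–f10 only.

Degenerate inputs follow fixed rules rather than propagating `NaN`: mask
columns that are constant (never or always missing) are excluded from the
f5/f6 correlation pairs, and f5 = f6 = 0 when no valid pair remains; f7
uses labeled rows only and is 0 when either side is constant; f8 is 0
when a class is absent.  The correlation estimator for f5–f7 is Pearson
on the binary masks — the choice was open, and Pearson keeps all three
correlation dimensions on one estimator.  f9 approaches 1 for very small
cohorts where most patients have unique patterns; the fingerprint stores
the row count as an attribute so users can weigh f9 accordingly, but no
small-sample correction is applied.

Little's test itself is computed by grouping rows by missingness pattern
and estimating the grand mean and covariance with
expectation–maximization under a multivariate normal model:
$d^2 = \sum_j n_j (\bar y_{j,\mathrm{obs}} - \hat\mu_{j,\mathrm{obs}})^\top
\hat\Sigma_{j,\mathrm{obs}}^{-1}
(\bar y_{j,\mathrm{obs}} - \hat\mu_{j,\mathrm{obs}})$, referred to
$\chi^2$ with $\mathrm{df} = \sum_j p_j - F$ ($p_j$ = observed variables
in pattern $j$).  Numerics: at most 100 EM iterations, convergence when
the largest parameter change falls below $10^{-6}$, a ridge of $10^{-8}$
on covariance diagonals before every inversion, fully missing rows
dropped, and zero-variance columns dropped with $F$ adjusted.  A single
pattern or $\mathrm{df} \le 0$ returns $p = 1$ with a flag.  The test's
documented blind spot is worth remembering: with *independent* columns it
has no power against univariate left-tail truncation, because every
pattern then sees the same truncated marginal; power comes from
correlated features.

## Degradation operators

* **MCAR injection** masks each observed cell independently with
  $p = (t - c)/(1 - c)$, where $t$ is the target global missing rate and
  $c$ the current one, so the expected post-injection rate is exactly
  $t$.  The target is the *total* rate, including pre-existing
  missingness; $t < c$ is an error, $t = c$ the identity.
* **MNAR injection** is noisy rank-threshold masking of the left tail,
  mimicking clinical patterns where low values are selectively
  unrecorded (albumin not ordered for patients presumed well-nourished).
  Per column, observed values get normalized ranks
  $(\mathrm{rank} - 0.5)/n_{\mathrm{obs}} \in (0,1)$ perturbed by
  Gaussian noise of $\sigma = 0.15$ (applied to the normalized ranks;
  the raw-rank alternative was rejected because it would make the noise
  scale depend on $n$), and exactly the
  $\lceil q \cdot n_{\mathrm{obs}} \rceil$ lowest noisy ranks are
  masked, with a uniform per-column rate $q = (t - c)/(1 - c)$.
  Exact-count masking makes the realized rate equal $t$ up to per-column
  rounding, which keeps rate attainment testable to a fraction of a
  percentage point.  Newly masked values are retained in an attribute so
  the left-tail bias is verifiable.
* **Label trimming** retains exactly `round(label_rate * N)` labels by
  class-stratified largest-remainder sampling; removed labels become the
  sentinel.  Feature values and the missing mask are never touched, and
  injection never touches labels.

MAR is deliberately *not* injected: it cannot be separated from MNAR by
any observed-data test, so the toolkit instead covers MAR by
construction in the synthetic module (below).  The six-condition
augmentation grid (`augmentation_grid()`) spans baseline (natural
missingness, 50% labels), light/moderate/heavy MCAR (10/30/50% missing
with 60/20/10% labels) and moderate/heavy MNAR (20/40% missing with
40/10% labels).

## Sweep harness and landscape

Performance is AUROC (with the Brier score alongside) averaged over
stratified 80/20 train/test splits of the labeled rows; unlabeled rows
join the training portion for methods that can use them and are never
evaluated.  The reference portfolio holds six lightweight pipelines —
mean-impute + logistic, missing-indicator logistic, and four
gradient-boosted-stump pipelines (mean, kNN and chained-equations
imputation, plus native missing handling via learned default split
directions).  Deep and graph methods are intentionally out of scope; the
`pipeline_method` contract (fit/predict closure, deterministic given a
seed, tolerant of any per-column missing rate below 1) is the plug-in
point.  The gradient-boosted stumps are implemented in-package because
no boosted-tree library is assumed; the learner presorts features once
and learns each split's missing-value direction from the data, which is
exactly the mechanism the "native missing" end-to-end method needs.

`winner_map()` averages AUROC across datasets per grid cell and reports
the winner distribution's Shannon entropy in bits; ties break by lower
Brier, then lexicographic method id (the tie rule was open and is now
deterministic and documented).  `degradation_emd()` normalizes a
degradation curve to a probability distribution over the missing-rate
grid and reports its 1-D Wasserstein distance from uniform; a flat curve
gives 0.  This reproduces the *ordering* semantics of degradation
sensitivity (steeper decline, larger EMD) but not necessarily any
particular printed magnitude, since the original normalization is not
fully specified — EMD values are therefore compared within one analysis,
never across toolkits.

The ten landscape descriptors d1–d10 (dispersion at the easiest/hardest
cell, AUROC/Brier degradation slopes, MNAR−MCAR gap, winner stability
and diversity, label-efficiency spread, Pareto-set size, calibration
discordance) summarize the sweep surface without naming methods; they
are invariant to method relabeling.  Two open points were fixed as
follows: "easiest/hardest" is (min miss, max label) / (max covered miss,
min covered label); and the Pareto axes are (mean AUROC up, mean Brier
down) rather than a runtime axis, keeping the descriptor
hardware-independent.  The per-method performance vector used for
dynamic distances is the instance's own-condition mean-AUROC vector;
multi-condition concatenation is possible through the same interface but
is not the default.

## Metric learning

With $s_i \in \mathbb{R}^{10}$ the static fingerprint and
$d^{\mathrm{dyn}}_{ij}$ the Euclidean distance between performance
vectors (rescaled by $\sqrt{M/m_{\mathrm{shared}}}$ under partial
overlap), the toolkit seeks simplex weights $w$ maximizing the Spearman
correlation $\rho$ between $d^{\mathrm{static}}_{ij}(w) = \lVert w \odot
(s_i - s_j) \rVert$ and $d^{\mathrm{dyn}}_{ij}$ over all unordered
pairs, plus a 1-nearest-neighbour oracle-method match reward:
objective $= -(0.7\rho + 0.3\,r_{\mathrm{match}})$.  Optimization is
differential evolution, strategy best1bin, population multiplier 15
(i.e. $15 \times 10$ members, the reference optimizer's convention),
mutation dithered in $(0.5, 1.0)$ per generation, crossover 0.7, 500
generations, tolerance $10^{-8}$, seed 42, parameterized in log10 space
with bounds $[-3, 3]^{10}$ and simplex-normalized afterwards.  The
optimizer is a self-contained best1bin implementation meeting that
contract (no DE library is assumed).  Log base 10 was an open choice;
it gives a symmetric three-decade range around 1.  Because distance
*rankings* are invariant to positive rescaling of $w$, the simplex
normalization is presentation, not optimization substance — a property
the tests assert directly.

Weights are re-learned inside every cross-validation fold, never on
instances from the held-out base group; the guard is asserted, not
assumed.

## Recommendation and safeguards

`recommend()` ranks methods by (vote count among the k nearest stored
instances' oracle methods, mean performance across those neighbours,
lexicographic id).  The default $k = 5$ is a declared choice — the
protocol does not pin it — and is exposed prominently.  The
out-of-distribution report flags each fingerprint dimension outside the
stored min–max envelope (strict, no slack) and distrusts the
recommendation when $\ge 3$ dimensions are flagged or the
nearest-neighbour distance exceeds the 95th percentile of stored
pairwise distances; distrusted queries should be validated with a
targeted sweep of the shortlist.  When no knowledge base is available at
all, `two_rule_recommend()` dispatches on Little's test: MCAR-consistent
data gets the strongest MCAR-regime default, rejecting data gets a
missingness-aware method.

## Evaluation harness

`lodo_evaluate()` holds out one base group at a time: all perturbed
siblings of a base dataset leave the training store together, so the
evaluation measures generalization to unseen cohorts rather than
interpolation between a dataset and its own perturbations.  Each test
instance is scored by its own performance-vector entry for the chosen
method; regret is the gap to the per-instance oracle and a win is an
exact oracle-method match.  The uniform-random baseline is evaluated
analytically (expected AUROC = per-instance mean; expected win = tied
winners / $M$), which removes needless Monte-Carlo variance from
reports.  `vbs_sbs_gap()` bounds what selection can gain;
`friedman_complementarity()` tests whether method rankings differ across
conditions; `block_bootstrap_delta()` resamples base groups with
replacement ($B = 2000$) for uncertainty on regret differences.

The oracle gap decomposes into a *noise* component — the expected excess
of the apparent best method's resampled mean over the true best mean
under split resampling, a declared operationalization of
repetition-variability regret — and a *selection* component, the
remainder.  Both are non-negative and sum exactly to the total gap; zero
split variance gives zero noise regret and an oracle recommender zero
selection regret.  Alternative readings (e.g. variance-share splits)
would not preserve that exact accounting identity, which is why this one
was chosen.

## The synthetic world

The generators state a world once and the tests live in it:

* `gen_complete_dataset()`: equicorrelated Gaussian features with a
  logistic outcome whose intercept is calibrated to the requested
  minority/majority ratio.  This is the minimal model supporting AUROC
  gradients and imputation differences.
* `gen_base_collection()`: 27 features by default, native missing rates
  drawn from 4–13% (the range of real multi-center ICU subsets), masked
  with exact cell counts as a 60% MCAR / 40% MAR mixture (the MAR part
  conditions on an always-observed driver feature).  The mixture default
  reproduces the empirical observation that native clinical data mostly
  *rejects* MCAR while staying configurable.  Class imbalance
  (0.3–0.8), feature correlation (0.1–0.4) and signal strength (0.8–2)
  are drawn per dataset; these are declared defaults for a realistic
  mid-sized EHR subset, not inferred from any source.
* `gen_mar_chain_dataset()`: diagnosis → procedure → lab conditional
  chain.  A lab value is missing exactly when no ordered procedure
  triggered it, so masking depends only on observed variables — MAR by
  construction, verified by stratified two-sample tests on the retained
  pre-masking values.  The chain matrices hold independent Bernoulli
  ordering/trigger probabilities (several procedures can be ordered per
  patient); lab means get a diagnosis-dependent shift so the MAR
  property is non-trivial (marginally, masked and observed values
  differ; conditionally on diagnosis they do not).
* `gen_planted_kb()`: fingerprints uniform in $[0,1]^{10}$ and
  performance vectors built through an orthonormal projection of the
  true-weighted fingerprints, so dynamic distances are exactly
  proportional to true-weighted static distances at zero noise.  This
  requires at least ten methods (an isometry into fewer dimensions does
  not exist), which the constructor enforces.

What the synthetic world does **not** emulate: longitudinal or
time-series structure, free text, realistic lab-value marginals, or any
specific EHR schema.  A green test therefore establishes that the
machinery is correct under the stated mechanisms — not that any
particular clinical dataset will enjoy the same regret.

## Numerical and scale choices

Exclusion rules for knowledge-base construction default to full method
coverage and a degeneracy floor of 0.55 best-method AUROC; both are
configurable because the criteria behind the original exclusions are
only named, not quantified.  The end-to-end test (20 synthetic bases →
six-method sweep on a 3×2×2 grid → augmentation → metric learning →
LODO report) runs with 12 features, 6 evaluation splits and 120 DE
generations per fold so the whole suite fits a desk-scale CPU budget;
the pipeline structure, seeds and thresholds are the same as at full
scale.  Acceptance quantities in `scripts/acceptance.R` are recomputed
from scratch at every run.

## Known limitations

The learned metric is linear in the fingerprint; non-linear feature
interactions are not captured.  MNAR injection models the left tail
only — right-tail truncation, trajectory-dependent dropout and
threshold censoring are unmodeled.  Little's test cannot separate MAR
from MNAR and loses power over numerous unique patterns.  kNN
recommendations systematically under-recommend rare winners, and all
conclusions are conditional on the knowledge base's coverage — which is
exactly what the OOD safeguards are for.
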