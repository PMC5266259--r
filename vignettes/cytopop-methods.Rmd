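---
title: "Methods: in silico communities for cytometric population identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico communities for cytometric population identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopop)
```

## The problem and the model

A flow cytometer characterises every cell of a bacterial sample by twelve
variables — four fluorescence detectors and two scatter detectors, each
recorded as pulse area (A) and height (H). Distinct bacterial populations
occupy partly distinct regions of this 12-dimensional space (their
"cytometric fingerprint"), but the regions overlap, so resolving a mixed
community into its member populations is a statistical problem, not a
deterministic one.

`cytopop` treats it as supervised single-cell classification. The key
construction is the **in silico community**: when each member population is
available as an axenic culture measured on its own, events subsampled from
those single-population measurements can be pooled into one labelled
dataset in which every cell's population of origin is known with certainty.
A classifier trained on this labelled aggregate predicts the origin of
cells in a genuinely mixed sample, and the community's composition follows
by counting predicted labels (the plug-in estimator
$\hat p_i = \#\{\text{cells predicted } i\}/N$).

Two classifiers are provided, deliberately standard:

* **Linear discriminant analysis** — class-conditional Gaussians with a
  shared covariance. No hyperparameters, natural multiclass behaviour,
  posterior probabilities via Bayes' theorem. The fit is delegated to
  `MASS::lda()`.
* **Random forest** — 200 unpruned trees on bootstrap samples, Gini split
  criterion, `mtry = floor(sqrt(K)) = 3` of the `K = 12` channels available
  per split; scores are tree-vote fractions. Delegated to
  `randomForest::randomForest()`. These defaults are the conventional
  preset; cross-validating `mtry` is known to buy well under a percentage
  point of accuracy on this kind of data, so no tuning machinery is
  included.

Features enter **raw** (no standardisation, no transformation) by default;
both classifiers are invariant enough in practice, and keeping the stored
intensities untouched makes results traceable to the files. An
`arcsinh_features` flag exists for users who want transformed features, off
by default.

## Preprocessing

Raw event clouds contain (in)organic debris and instrument noise
concentrated at low fluorescence. Denoising is **reproducible digital
gating**: a fixed simple polygon in the arcsinh-transformed FL1-H x FL3-H
plane, applied identically to every replicate of a culture and to every
sample of a gradient. The arcsinh (cofactor 1, i.e. plain `asinh(x)`) is
the standard display scale: linear near zero, logarithmic for large
intensities. Gate vertices are inputs (a YAML config per taxon), because
appropriate gates depend on the instrument and stain; the packaged default
is the rectangle $[1, 20]^2$ in arcsinh space, which separates the
low-fluorescence debris corner from stained cells.

Numerical conventions fixed for determinism:

* events exactly on a gate edge or vertex count **inside** (the usual
  gating-tool convention; some point-in-polygon routines leave the boundary
  undefined, so the test is implemented with an explicit on-segment check);
* degenerate (zero-area) and self-intersecting polygons are rejected at
  construction;
* gating partitions events exactly — inside and outside are disjoint, their
  union is the input, order is preserved.

Replicates of a culture are gated first, then pooled; all subsampling
happens downstream, seeded.

## Community construction

* **Even communities**: `n_per_pop` = 5,000 cells per culture by default,
  drawn uniformly *without replacement* from the pooled events, so an
  S-population community holds $N_{tot} = S \times 5{,}000$ cells at
  composition $1/S$ each. A pool smaller than the request is an error by
  default (`allow_short = TRUE` takes what is available and records the
  achieved composition).
* **Train/test split**: 70/30 by default. The split is **stratified** by
  population: `round(0.7 * n_i)` per taxon. Stratification is a design
  choice — an unstratified split would let composition drift in small
  communities and make per-class metrics noisier; with 5,000-cell classes
  the difference is negligible, which is why it is safe as a default.
* **Abundance gradients**: 13 two-population communities at
  $p_1 \in \{0.01, 0.05, 0.10, \dots, 0.90, 0.95, 0.99\}$, 10,000 cells
  each. Counts are `round(p1 * n_total)` for the first taxon (round-half-even,
  R's `round()`) and the exact remainder for the second, so totals are
  exact and RMSEs comparable across levels.
* **Richness scans**: all taxon combinations of size S when there are at
  most 150 of them, otherwise 150 sampled uniformly *distinct*
  combinations (via ranks in the combinatorial number system, so nothing
  is materialised unnecessarily). With 20 taxa: 190 pairs at S = 2; 20 and
  1 combinations at S = 19 and 20.

Every stochastic operation takes an explicit seed; the experiment runners
derive per-task seeds from a root seed by stable string hashing
(`derive_seed()`), so whole experiments are bit-reproducible and adding a
task never shifts the seeds of others.

For gradient recovery the classifier is trained on the **full** even
community (no held-out split — the gradient itself is the test set), and
training draws are made disjoint from the gradient draws whenever the pool
is large enough (training cells first, gradient from the remainder). This
mirrors an in vitro gradient, whose cells are physically distinct from the
separately measured axenic cultures. A fresh-culture batch effect can be
emulated by simulating a panel with a nonzero `drift_model()` for the
gradient pools.

## Performance measurement

* **Accuracy** is the fraction of correctly labelled cells. The
  macro-averaged one-vs-rest form (averaging
  $(tp_j + tn_j)/(tp_j+tn_j+fp_j+fn_j)$ over classes) is implemented as
  `accuracy_macro()` for cross-checking; it coincides with the fraction
  correct for S = 2 but inflates with S because it credits true negatives,
  so it is not the headline number.
* **AUC** (binary only) is computed by the rank formula — the Mann–Whitney
  U statistic over $n_+ n_-$, ties counted half. It is the probability that
  a random positive outscores a random negative, is insensitive to class
  imbalance, and invariant under monotone score transforms. No multiclass
  AUC is offered.
* **Gradient RMSE**: $\sqrt{\sum_{i=1}^n (p_i - \hat p_i)^2 / n}$ over the
  n communities of a gradient.
* **Confusion matrices** are reported row-normalised ($m_{ij}$ = fraction
  of population i predicted as j) with raw counts retained; zero-support
  rows are all-zero and flagged rather than NaN.
* Across many communities, summaries are mean ± SD; the richness scan's
  "68% band" is mean ± 1 SD of per-community accuracies.

## Diversity error propagation

The Hill number of order one, $D_1 = \exp(-\sum_i p_i \ln p_i)$, is the
effective number of equally abundant populations (1 ≤ D1 ≤ S, maximal at
evenness, $0 \ln 0 := 0$). Flow-cytometric cell counts carry a relative
instrumental error of at most about 5%; since an abundance is a ratio of
two counts, $\sigma^2_p = 2\,\varepsilon_I^2 p^2$ with
$\varepsilon_I = 0.05$ by default. Treating the abundances as independently
measured, the delta method gives

$$\sigma^2_{D_1} = D_1^2 \sum_i (\ln p_i + 1)^2 \sigma^2_{p_i},$$

with the i-th term zero when $p_i = 0$ (its limit) — note each term also
vanishes at $p_i = e^{-1}$, where D1 is locally insensitive to that
abundance. For S = 2 this reduces to a closed form in $p_1$ alone
(`var_d1_binary()`), which the general formula matches to machine
precision. Confidence intervals assume approximate normality of the
propagated error: 68% as $D_1 \pm 1.0\,\sigma_{D_1}$ and 95% as
$D_1 \pm 1.96\,\sigma_{D_1}$ — the z-multipliers are a package choice, as
is checking the construction by Monte Carlo (`d1_coverage_mc()`): both
counts behind each abundance are perturbed by independent 5% multiplicative
Gaussian noise and D1 recomputed; at $p_1 = 0.3$ the empirical 95% coverage
is nominal to within MC error. The delta approximation degrades as any
$p_i \to 0$ or 1 (the noise becomes skewed relative to the interval), so
intervals at the 1%/99% gradient ends are indicative rather than exact.

## The synthetic-data generator

`simulate_panel()` emulates what the framework consumes — per-culture,
per-replicate event files with ground truth on the side — not the
biophysics of staining. The model:

* each population is a mixture of 1–3 Gaussian components in arcsinh space
  (real fingerprints show multi-modal smears from cell-size and cell-cycle
  variation); draws are back-transformed with `sinh` and clipped at 0;
* area channels are tied to height channels as $A = H + 0.2 + e$,
  $e \sim N(0, 0.15^2)$ in arcsinh space — an affine gain ≥ 1 on the raw
  scale, giving the strong A–H correlation of pulse processing;
* per-replicate technical drift: one additive shift and one multiplicative
  factor per channel per replicate (shared across its events), emulating
  bleaching/settling between measurements; defaults are zero;
* debris: a binomial fraction (default 5%) of events drawn diffusely in
  the low-FL1/low-FL3 corner below the default gate floor, so gating can be
  tested against known ground truth;
* default sizes mirror practice: 10,000 cells per replicate, duplicate
  measurements, 20-taxon collections.

The `preset_pairs()` separability presets (`low`, `medium`, `high`,
`none`) shift the informative FL1-H/FL3-H means of the second population by
$\delta$ = 0.33, 0.85, 1.80 and 0 (arcsinh units) against a within-population
SD of 0.45. Because only parallel mean shifts separate the pair and the
A-channels add no independent signal, the Bayes accuracy is
$\Phi(\delta/(\sqrt 2 \sigma))$; the three $\delta$ values were chosen from
that relation to target reference random-forest held-out accuracies of
roughly 0.6–0.8, 0.85–0.95 and ≥ 0.98 on an even 10,000-cell community,
verified once with the reference configuration (200 trees, mtry 3, seed
20170106) and frozen.

What the simulation does **not** model: spillover/compensation structure,
heavy non-Gaussian tails, time drift within a measurement, doublets, and
day-scale biological variability of cultures. Passing tests on synthetic
panels therefore demonstrate the pipeline's correctness and its behaviour
under controlled overlap — not instrument-grade performance on real
cultures, which depends on fingerprints and gates the user supplies.

## Problem sizes in the tests and acceptance script

The shipped tests run the full pipeline at reduced sizes (hundreds of
cells per population, 25–100 trees) chosen so the whole suite exercises
every contract in well under a minute; the quantitative end-to-end checks
(gradient recovery, chance-level behaviour, Monte-Carlo coverage) use the
standard sizes — 5,000 cells per culture, 10,000-cell gradient
communities, 10,000 MC draws. The acceptance script runs the pairwise scan
of a 20-population panel at 1,000 cells per population (190 pairs × 2
classifiers), and the three preset gradient recoveries at full size; these
sizes are the package's reporting defaults and reproduce identically under
a fixed root seed.

## Known limitations

* FCS support is a minimal single-dataset 3.0/3.1 list-mode codec (float
  data, little/big endian): no multi-dataset files, no FCS 2.0/3.2, no
  spillover handling. Files written by mainstream acquisition software in
  FCS 3.0/3.1 list mode read fine; exotic keyword usage may not.
* LDA assumes shared-covariance Gaussians; strongly non-elliptic
  fingerprints favour the random forest (visible as the LDA–RF gap on the
  `high` preset).
* The plug-in composition estimator is biased when classes are confusable
  (predictions are pulled toward the classifier's prior — the even training
  composition); the gradient RMSE reports exactly this bias plus noise.
  No correction (e.g. inverting the confusion matrix) is applied, keeping
  the estimator the transparent count it is.
* Diversity intervals reflect instrument counting error only, not
  classification error or biological replicate variability.
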