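---
title: "Methods: building and evaluating cross-species epigenetic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating cross-species epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockforge)
```

## The model

An epigenetic clock is a penalized linear predictor of age from CpG
methylation beta values (the fraction of methylated signal at a CpG, in
[0, 1]). Given a samples × probes beta matrix $X$ and a transformed age
target $y$, clockforge fits

$$\hat y = \beta_0 + X\beta$$

by elastic-net regression with the mixing parameter fixed at
$\alpha = 0.5$, midway between ridge and lasso. $\alpha$ is a convention
of this family of clocks, not a tuned quantity; only the penalty
strength $\lambda$ is chosen, automatically, by tenfold internal
cross-validation minimizing mean squared error (the `lambda.min` rule of
`glmnet::cv.glmnet`). Probes with nonzero coefficients constitute the
clock; typical clocks retain a few dozen to a few hundred CpGs out of
tens of thousands.

Three targets are supported, chosen by the scientific question:

* **raw_age** — age in years, untransformed. Appropriate for a
  single-species clock over a moderate age range.
* **loglinear** — for dual-species chronological clocks. Epigenetic
  change is fast during development and slower in adulthood, and two
  species reach maturity at very different ages, so each species' ages
  are mapped through
  $$F(a) = \begin{cases}
    \log\frac{a + o}{m + o} & a < m\\[2pt]
    \frac{a - m}{m + o} & a \ge m
  \end{cases}$$
  with $m$ the age of sexual maturity and $o \ge 0$ an offset keeping
  newborn ages finite. The two branches meet at $F(m) = 0$ with common
  slope $1/(m+o)$, so $F$ is continuous, differentiable and strictly
  increasing, and has the exact inverse implemented in
  `loglinear_inverse()`. Predictions are mapped back to years with each
  sample's own species parameters. Defaults shipped with the synthetic
  panels are $m = 1$ y for cats and $m = 15$ y for humans with $o = 0$;
  these are package defaults chosen as round biological values, and both
  are configurable per species.
* **relative** — age divided by the species' maximum recorded lifespan
  (30 y for domestic cats, 122 y for humans, following the values used
  in comparative-aging databases). The ratio is dimensionless, aligns
  species with very different lifespans on a common [0, 1] scale, and is
  trained and reported untransformed. Predictions are deliberately not
  clamped: a value above 1 is information, not an error (a `floor_zero`
  reporting flag exists for negative chronological predictions).

A deliberate non-assumption: no nonlinear cross-species age alignment is
fitted. The relative-age construction assumes only that proportion of
lifespan is comparable across species.

## External cross-validation

Fitted-set accuracy of a penalized model is optimistic, so accuracy is
reported from *external* cross-validation in which the held-out sample
is never seen by the model that predicts it:

* `loocv()` — leave one sample out, refit (including the internal
  $\lambda$ search), predict it; iterate over all samples.
* `kfold_cv()` — random folds, by default stratified by species so every
  training fold contains both species of a dual-species clock; fold
  sizes within a stratum differ by at most one. `k = n` reduces exactly
  to leave-one-out (the assignment becomes deterministic and
  seed-independent). Whether the original ten-fold scheme stratified by
  species is not documented; stratification is this package's choice and
  can be switched off.

Two metrics are reported overall and per species: Pearson correlation
R between prediction and truth, and the median absolute error (MedAE).
The pair is deliberately decoupled — R is invariant to any affine
miscalibration of the predictions while MedAE is not — because their
divergence is precisely the signature of a clock transferred to a
species outside its training set: rank-order information survives
(high R) while calibration does not (high MedAE). `transfer_evaluate()`
reports R, MedAE, mean signed bias and the prediction-on-truth slope per
species; `recalibrate_linear()` offers a clearly labeled post-hoc linear
correction whose corrected MedAE is an in-sample quantity, excluded from
any accuracy claim.

One subtlety worth knowing: under a pure-noise null, cross-validated
predictions are systematically *anti*-correlated with truth, because
each fold's fit shrinks toward the mean of a training set that excludes
the held-out samples (an intercept-only model under leave-one-out gives
exactly R = −1). The null expectation for cross-validated R is therefore
"not positive", not "near zero", and the test suite asserts it in that
form.

## The EWAS screen

Per CpG, association with age is the Pearson correlation test:
$r$, then $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom,
the two-sided $p$, and the signed normal-equivalent
$z = \mathrm{sign}(r)\,\Phi^{-1}(1 - p/2)$. $z$ is computed on the
log-$p$ scale so it does not underflow, and is capped at
$z_{\max} = 40$ with a saturation flag; printed $p$ values below about
$10^{-308}$ underflow double precision to 0, but thresholding and
ranking operate on quantities that do not. Per-tissue results are
combined with Stouffer's method,
$Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ (equal weights by default);
probes absent in a tissue contribute nothing rather than $z = 0$.

Genome-wide significance uses the fixed threshold $p < 10^{-8}$ rather
than an FDR procedure, exposed as a parameter. `select_top_cpgs()` keeps
up to 500 probes per direction (hyper-/hypomethylating, by the sign of
$z$), most extreme $|z|$ first, with ties broken lexicographically by
probe id so the selection is deterministic and order-invariant.
`region_summary()` and `island_association_summary()` then summarize the
genomic context of the selected CpGs: counts per region class relative
to the closest transcription start site, the proportion hypermethylated
per region, and an island-versus-other contrast of the $z$ distribution
tested with a two-sided Wilcoxon rank-sum test (the comparison is
distributional; the rank-sum test is this package's choice of test).

## Quality control

`interarray_correlation()` computes pairwise Pearson correlation between
samples over shared non-missing probes; `average_linkage_tree()`
clusters samples with average linkage (UPGMA) on `1 − correlation`.
The original visual check — a sample whose annotated sex disagrees with
its position in the dendrogram — is operationalized deterministically in
`flag_sex_mismatches()`: a sample is flagged when its annotated sex
differs from the strict majority sex of its $k = 5$ nearest neighbors by
inter-array correlation (ties do not flag; neighbors are restricted to
samples with known sex). The value of $k$ is this package's choice; no
threshold for the visual call was ever stated.

`oob_trait_accuracy()` fits a random forest (500 trees, $\sqrt p$
candidate features per split) and reports the out-of-bag
misclassification rate. OOB votes are tallied per sample and ties are
broken toward the alphabetically first class, making the rate
reproducible given the seed. The `subset` argument supports analyses of
a trait confounded with age (e.g. restricting neuter-status prediction
to young animals).

## The synthetic panel generator

Real consortium methylation profiles are not redistributable at desk
scale, so every downstream stage is exercised on synthetic panels with
known ground truth. `generate_panel()` emulates a conserved-CpG
mammalian array:

$$\beta_{ij} = \mathrm{clip}\big(b_{0j}(s_i) + \mathrm{slope}_j \cdot
\mathrm{relage}_i + \delta_j \cdot \mathbb{1}[\mathrm{male}_i] +
\varepsilon_{ij},\ 0,\ 1\big), \qquad
\varepsilon_{ij} \sim \mathcal N(0, \sigma^2)$$

* Aging is linear in **relative age** (age / max lifespan), not raw age,
  so that shared age probes are genuinely cross-species conserved — the
  premise that makes dual-species clocks possible.
* Age probes (half gaining, half losing methylation) change by
  `age_effect_size` (default 0.3 beta units) over the full relative-age
  range, with per-probe magnitudes drawn in [0.5, 1] × effect size. A
  `shared_fraction` of them have identical slopes in all species; the
  rest keep the probe-level sign but draw independent magnitudes per
  species, so ground-truth signs stay well defined everywhere.
* Sex probes differ by `sex_effect_size` (default 0.15) between sexes;
  species-marker probes carry Gaussian per-species offsets (s.d. 0.1)
  that make samples cluster by species; everything else is null.
* Baselines are uniform in [0.1, 0.9] (age-probe baselines positioned so
  the lifespan excursion stays in range), and noise is Gaussian with
  s.d. 0.03 then clipped to [0, 1] — simpler than a Beta observation
  model and adequate for testing; the clipping frequency is reported and
  stays well under 5 % at defaults. Species can additionally carry a
  constant `baseline_shift` (modeling a systematic platform/species
  offset) or have their age signal switched off entirely
  (`has_age_signal = FALSE`), the two handles used to construct
  transfer-evaluation panels and their negative controls.
* Probe annotation is generated alongside with hypermethylating age
  probes biased toward promoters/5'UTRs and CpG islands and
  hypomethylating ones toward gene bodies and intergenic open sea,
  mirroring the genomic distribution typical of aging methylation, so
  the context summaries have signal to find.

Default study-scale conditions used by the test suite and the acceptance
script: 130 cats (ages 0.21–20.9 y, lifespan 30 y) plus 300 humans (ages
0–93 y, lifespan 122 y), 4,000 probes of which 300 are age probes, noise
s.d. 0.03. The human arm is scaled down from the original cohort's
n = 1211 to keep a full leave-one-out run at desk scale; the cat arm
matches the original design. Effect-size defaults are chosen for test
power — no per-probe effect-size distribution of the real data is
published, and these values are never presented as estimates of it.

What the generator does **not** emulate: array chemistry, detection
p-values, batch/chip structure, tissue effects within a species (the
human samples carry a tissue label but no tissue effect, matching
tissue-agnostic training), breed structure, or Beta-distributed noise.
Passing tests on these panels therefore demonstrate the correctness and
calibration of the *procedures*, not the accuracy of any clock on real
arrays.

## Numerical and design choices

* Internal penalty selection: `lambda.min`, tenfold, MSE loss; the rule
  was never stated in the original description beyond "automatic", so
  the glmnet default path and the minimum-CV rule are adopted.
* Samples with weight 0 are dropped before fold assignment, so
  dual-species training with one species zero-weighted reproduces the
  single-species fit coefficient-for-coefficient.
* No sample weighting between species despite unbalanced n; the
  imbalance itself is part of the emulated design.
* Missing betas are mean-imputed per probe at training time with a
  logged count; prediction errors on missing model probes by default,
  with an opt-in imputation.
* Clock files round-trip decimals through 17-significant-digit text, so
  a written-then-read model predicts bit-identically.
* All randomness flows through named integer seeds; the pipeline driver
  (`run_pipeline()`) hashes every output into a manifest with relative
  paths, making end-to-end bit-identity of two runs a testable property.
* Demo problem sizes (`make_demo()`: 40 cats + 60 humans, 600 probes,
  5-fold CV) are chosen so the full pipeline finishes in about a minute
  on a laptop core.

## Known limitations

* The package evaluates clocks against chronological age only; no
  age-acceleration-versus-outcome analysis is included, as none exists
  in the source design.
* The log-linear transform's published parameter values live in an
  unreleased supplement; the functional form here is the standard
  construction (log below maturity, linear above, continuous at
  maturity) with per-species parameters, and nothing downstream depends
  on the exact original values.
* Probe-to-genome alignment, gene-level enrichment, motif discovery and
  chromatin-state enrichment are out of scope; the annotation consumed
  here is a plain table produced upstream.
* Reported transfer numbers on synthetic cheetah-like species mirror the
  qualitative high-R/high-MedAE phenomenon, not any published per-species
  figure.
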