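---
title: "Methods: predicting rapid cognitive decline from EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting rapid cognitive decline from EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidprog)
library(dplyr)
```

`rapidprog` implements an end-to-end workflow for identifying rapid
progression (RP) of Alzheimer's disease and related dementias from electronic
health records: cognitive scores are pulled out of clinical-note text, a
decline-rate rule labels each patient, structured features are prepared and
filtered, an imbalance-aware duplication sampler rebalances the training set,
an autoencoder-based classifier predicts RP, a logistic ensemble stacks two
instrument-specific models, and additive attributions explain the
predictions. Because real dementia EHR cohorts are protected, the package
ships a synthetic-cohort generator with the statistical structure the
pipeline assumes, so every stage is testable offline.

## Labeling by cognitive decline rate

For each patient and instrument (MMSE or MoCA, both 0--30 points, lower =
worse), the earliest assessment is the baseline (its date the *index date*).
The target is the earliest follow-up at least six months later. The
progression rate is

$$P_{rate} = \frac{score_{base} - score_{target}}{\Delta t \,[\text{years}]},$$

and a patient is a rapid progressor when $P_{rate} \ge 3$ points/year.
Exclusion rules: a single assessment excludes the patient; with exactly two
assessments the second must fall at least six months after the first; with
more, the earliest qualifying follow-up is the target. Patients assessed with
both instruments but labeled discordantly are excluded from the composite
group.

Decisions the rule set leaves open, and how this package resolves them:

* **"Six months"** is 183 days (configurable), and years are days/365.25.
* **MoCA threshold strictness**: the inclusive comparison ($\ge 3$) is the
  default for both instruments; `strict_moca = TRUE` switches MoCA to a
  strict $> 3$. The two readings differ only for rates exactly at the
  threshold.
* **Same-day duplicate scores** collapse to the lower score — the
  conservative choice (a worse score is more likely to reflect genuine
  impairment than a practice effect), and deterministic.
* **ICD matching** is exact on normalized codes, not prefix-based, because
  the diagnosis filters enumerate child codes explicitly.

The note extractor is a small, documented bank of Perl-compatible regular
expressions (`default_score_patterns()`); users can extend it. It is not a
clinical NLP system: it guarantees a round trip with the note templates in
this package and recognizes common "MMSE score: 24/30"-style phrasings, no
more.

## Feature preparation

Stages run in a fixed order — missingness filter, min-max scaling, one-hot
encoding, selection, KNN imputation — with every statistic fitted on
training rows only and frozen. Imputation runs last so the selection tests
can use pairwise-complete observations rather than imputed values.

* **Missingness filter**: a column with *strictly more than* 30% missing
  values is dropped (exactly 30% is kept).
* **Min-max scaling** maps continuous columns to [0,1] with training-set
  minima/maxima; out-of-range values at transform time are deliberately not
  clipped, so a shifted test distribution remains visible.
* **One-hot encoding** emits one 0/1 indicator per training-observed level;
  a missing categorical value makes the whole indicator block missing, and
  an unseen level yields all-zero indicators with a warning.
* **Selection** drops a column that fails any applicable rule: variance
  below 0.1; absolute Pearson correlation with the label below 0.01;
  chi-squared p ≥ 0.05 (2×2 table, indicator columns); one-way ANOVA
  p ≥ 0.05 (continuous columns). One subtlety: after min-max scaling no
  unimodal continuous variable can reach variance 0.1 (even a uniform
  variable on [0,1] has variance 1/12), so applying the variance rule to the
  scaled values would silently delete every continuous feature. The variance
  statistic is therefore computed on the raw, pre-scaling values for
  continuous columns; for indicators it is the 0/1 variance $p(1-p)$, which
  acts as a rare-level filter (dropping levels with prevalence outside
  roughly 11%--89%).
* **KNN imputation** (k = 3) fills a missing cell with the mean of the
  column's values among the k nearest rows, with Euclidean distance computed
  over mutually observed columns and normalized by the number of shared
  columns. Ties break on row index; columns with fewer than k observed
  values fall back to the column mean with a warning. When a fitted pipeline
  is applied to new rows, neighbors are searched among the training rows
  only, and a row with no observed value at all falls back to training
  column means (the standalone operation rejects such rows instead).

## Hybrid upsampling (SCUS)

Minority-class duplication to a target positive-to-negative ratio $p_{nr}$
(default 1.0), combining two rankings of the *real* minority rows — no
synthetic interpolation is ever performed, so no impossible feature
combinations can enter training:

* **Clustering component** ($w_{clu}$, default 0.8): k-means with
  $m = \min(N_{clu}, |X_{min}|)$ clusters on the minority rows; each
  cluster contributes the row nearest its centroid; candidates are
  replicated cyclically to the required count.
* **Similarity component** ($w_{sim} = 1 - w_{clu}$): minority rows ranked
  by descending mean cosine similarity to all majority rows, top ranks
  duplicated (cycling when more rows are needed than exist).

The number of *additional* rows is
$N_{desired} = \max(0, \text{round}(p_{nr}\,|X_{maj}|) - |X_{min}|)$, split
as $N_{clu} = \text{round}(w_{clu} N_{desired})$ and
$N_{sim} = N_{desired} - N_{clu}$, which conserves the total exactly and
makes the final minority count equal the target ratio (counting the desired
total without subtracting the existing minority rows would overshoot the
ratio once the original minority rows are unioned back in). Comparators with
the same ratio guarantee: uniform random duplication, similarity-only,
dissimilarity-only (ascending ranking), clustering-only, and `default`
(no resampling).

Numerical details: k-means uses a fixed seed, Lloyd iterations and 10
restarts; centroid-distance and similarity ties break on row index. Cosine
similarity is undefined for zero-norm rows; the exported
`similarity_upsample()` rejects them, while the pipeline entry points use a
documented `rank_last` policy because min-max scaling can legitimately
produce all-zero rows (a patient at the training minimum of every retained
feature).

## The autoencoder-based classifier

With rows as samples,

$$h = \mathrm{ReLU}(W_2\,\mathrm{ReLU}(W_1 x + b_1) + b_2), \qquad
\hat x = \mathrm{ReLU}(W_4\,\mathrm{ReLU}(W_3 h + b_3) + b_4),$$
$$\hat y = W_6\,\mathrm{Dropout}(\mathrm{ReLU}(\mathrm{BatchNorm}(W_5 h + b_5))) + b_6,$$

trained on the joint objective

$$\mathcal{L} = \lambda\,\mathcal{L}_{cls} + (1-\lambda)\,\mathcal{L}_{rec},$$

where $\mathcal{L}_{rec}$ is the mean squared reconstruction error over all
samples and features and $\mathcal{L}_{cls}$ is the focal loss
$-\alpha_t (1-p_t)^\gamma \log p_t$ with $p_t = \sigma(\hat y)$ for
positives and $1-\sigma(\hat y)$ for negatives, $\alpha_t = \alpha$ for
positives and $1-\alpha$ otherwise. At $\gamma = 0, \alpha = 0.5$ the focal
loss is exactly half the binary cross-entropy, which the test suite asserts
over random logits.

Defaults follow the training recipe the method was designed with: Adam at
learning rate 0.001, batch size 16, up to 80 epochs, dropout 0.6 in the
classifier MLP only, $\lambda = 0.5$, $\alpha = 0.3, \gamma = 2.0$ (the
MMSE-group setting; 0.5/3.0 is the MoCA-group setting), and early stopping
when the validation *total loss* fails to improve for 20 consecutive epochs
(patience 0 stops at the first non-improving epoch); the best-validation
parameters are returned. Choices the recipe leaves open:

* **Hidden sizes**: encoder $d \to \max(32, d/2) \to \max(16, d/4)$ with the
  latent size capped at $d - 1$; classifier hidden width 32. Configurable.
* **Optimizer**: Adam, matching the stated learning rate.
* **Early-stopping criterion**: validation total loss, minimized; the
  alternative (validation F1) is not the default because it is stepwise and
  noisy at these validation sizes.
* **Reconstruction loss** is computed on the same (possibly upsampled)
  training batches as the classification loss.
* **Initialization**: He-normal weights; hidden biases start at 0.01 rather
  than 0 because an all-ReLU encoder with zero biases can be born dead (every
  latent unit rectified for every input), after which pure-reconstruction
  training cannot recover.
* **Numerical guards**: $p_t$ is clamped to $[10^{-7}, 1-10^{-7}]$ inside
  the logarithm; batch norm uses $\varepsilon = 10^{-5}$, biased batch
  variance, and running statistics with momentum 0.1 (frozen in eval mode,
  so predictions are deterministic and row-order invariant).

The whole training loop is bit-reproducible under a fixed seed: the seed
controls initialization, epoch shuffling and dropout masks, and all
randomness is scoped so callers' RNG state is untouched. Gradients —
including the batch-norm backward pass — are verified against central finite
differences in the test suite.

## Two-instrument ensemble

Patients labeled concordantly under both instruments (the composite group)
get predicted probabilities from the MMSE-based and the MoCA-based model;
the pair $(p_{MMSE}, p_{MoCA})$ feeds an unregularized logistic regression.
Because the evaluation protocol for this group is otherwise unspecified, the
stacker is fitted on a seeded 70/30 split inside the composite group and
evaluated on the held-out 30% — in-sample evaluation would be optimistic
with so few positives. With only two features no regularization is needed;
an optional L2 flag is deliberately omitted rather than half-supported.

## Attribution

`attribute_features()` produces additive per-feature explanations in the
DeepLIFT/DeepSHAP family: multipliers are propagated backwards through the
eval-mode encoder and classifier, with the rescale rule at every ReLU and
exact affine handling of batch norm. For each background row the
contributions satisfy summation-to-delta *exactly*, so after averaging over
the background set

$$\text{base} + \sum_j \phi_j(x) = f(x)$$

holds to floating-point precision on every explained row — the local-accuracy
contract, asserted at $10^{-3}$ in the tests and observed at $\sim 10^{-15}$.
Attributions are computed on the logit scale by default; the probability
scale applies the rescale rule through the final sigmoid and is therefore
also exact, not an approximation. For a model operating in a single linear
region the attributions reduce to the closed form
$w_j (x_j - \overline{bg}_j)$, and features with no path through the network
receive exactly zero — both are tested. The default background is a seeded
subsample of up to 100 training rows; per-feature importance is the mean
absolute attribution, with descending order and index tie-breaks.

## The synthetic cohort generator

`simulate_cohort()` draws patient classes as Bernoulli at the configured RP
prevalence (default 0.18, matching the imbalance the pipeline targets), then
gives each patient-instrument pair a linear score trajectory at a rate drawn
uniformly from the class support — RP 4.5--7.5 points/year, non-RP −0.5--1.4
— with Gaussian noise (sd 1 point), integer rounding, and clipping to 0--30.
Structured features are a mix of continuous columns (informative ones
shifted by the effect size between classes) and 2--5-level categoricals
(informative ones with class-tilted level probabilities), with
completely-at-random missingness. Notes are rendered from templates that the
extractor provably round-trips.

Two design points matter for interpreting test results:

* **Recoverability by construction.** Trajectory noise is applied only to
  assessments that are neither the baseline nor the qualifying target; the
  two anchors stay on the rounded linear trajectory. With unrestricted
  Gaussian noise on the anchors, a 100% label round trip would be impossible
  (noise tails cross any threshold), so the generator guarantees it
  structurally: the default rate supports sit ≥ 1.5 points from the 3
  points/year threshold, while integer rounding can perturb the observed
  rate by at most ~1.1 points/year at the minimum 330-day gap.
* **What passing tests do and do not show.** The generator emulates
  imbalance, separable decline rates, mixed-type features with MCAR
  missingness, and score-bearing note snippets. It does not emulate
  informative missingness, visit-level temporal structure, ICD-coded
  encounter streams, label noise near the threshold, or realistic clinical
  language. Green tests therefore demonstrate that the machinery is correct
  and that the sampler/model behave as designed under the stated
  assumptions — not that the pipeline reaches any particular performance on
  real EHR data.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at desk scale, as
the package's own choice of demonstration sizes: cohorts of 150--1,000
patients, 20--50 features, 8--80 training epochs, 5--25 replicate seeds for
the directional comparisons, and brute-force oracle checks on instances of
up to 8×8 rows (where exhaustive ranking is feasible). The sampler
comparison uses prevalence 0.15 and effect size 1.0 — deliberately hard
enough that the no-resampling baseline often predicts no positives at the
0.5 threshold, which is exactly the failure mode imbalance-aware sampling
exists to fix.

## Known limitations

* The note extractor is a pattern bank, not a general clinical NLP method.
* The variance-rule scale choice (raw variance for continuous columns) is a
  documented reading; applying the rule on scaled values is not supported
  because it degenerates.
* Pure-R training is practical up to a few thousand rows and a few hundred
  features; beyond that, batch sizes and epoch counts should be tuned, or
  the model swapped for a compiled backend.
* The stacking ensemble supports exactly two instruments.
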