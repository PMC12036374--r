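# rapidprog

Alzheimer's disease and related dementias (AD/ADRD) progress at very
different speeds; the patients who decline fastest — *rapid progressors*
(RP), conventionally those losing ≥ 3 points per year on the MMSE or MoCA —
need to be found early, but they are a small minority in any clinic's
records, and the cognitive scores that define them are often buried in
free-text notes. `rapidprog` is an R package for clinical informaticians and
biostatisticians that implements this prediction problem end to end on
electronic health records:

1. **Score extraction** — a documented, extensible regex pattern bank pulls
   MMSE/MoCA scores out of clinical-note text.
2. **Cohort labeling** — exclusion rules (single assessment; follow-up
   sooner than six months), baseline/target selection, and the decline rate
   `P_rate = (score_base − score_target) / years`, thresholded at 3
   points/year.
3. **Feature preparation** — min-max scaling, one-hot encoding, a 30%
   missingness filter, four selection rules (variance < 0.1, |Pearson r| <
   0.01, chi-squared p ≥ 0.05, ANOVA p ≥ 0.05), and k-nearest-neighbor
   imputation (k = 3), all fitted on training rows only.
4. **Imbalance-aware upsampling** — a hybrid sampler that duplicates real
   minority rows chosen by k-means-centroid proximity (weight `w_clu`) and
   by highest mean cosine similarity to the majority class (weight
   `w_sim = 1 − w_clu`), reaching a target positive-to-negative ratio
   `p_nr`; plus random / similarity / dissimilarity / clustering
   comparators. No synthetic interpolation, ever.
5. **An autoencoder-based classifier** — encoder
   `h = ReLU(W₂ ReLU(W₁x + b₁) + b₂)`, symmetric decoder, and an MLP head
   with batch norm and dropout, trained with the joint objective
   `L = λ·Focal(ŷ, y) + (1−λ)·MSE(x, x̂)` (focal loss
   `−α_t (1−p_t)^γ log p_t`), Adam, seeded minibatches, and early stopping
   on validation loss. Forward, backward (including batch norm), and the
   optimizer are implemented in the package and verified against finite
   differences.
6. **A two-instrument ensemble** — a logistic regression stacked on
   `(p_MMSE, p_MoCA)` for patients labeled concordantly by both instruments.
7. **Attribution** — additive per-feature explanations (DeepLIFT-rescale
   family) whose contributions plus a base value reconstruct the model
   output exactly (local accuracy), with top-k importance rankings and
   cross-model comparison.

Real dementia EHR cohorts are protected, so the package includes a
synthetic-cohort generator (`simulate_cohort()`) producing longitudinal
score timelines, note snippets, mixed-type features with missingness, and
ground-truth labels that the labeling module provably recovers — every stage
is testable offline.

## Worked example

```r
library(rapidprog)
library(dplyr)

cohort <- simulate_cohort(synth_config(n_patients = 300, seed = 42))
cohort
#> <synth_cohort>
#>   patients:    300  (55 RP / 245 nonRP)
#>   assessments: 1356
#>   features:    30 columns

# label every patient x instrument from the assessment timelines
labels <- label_assessments(cohort$assessments)
count(filter(labels, !excluded), instrument, label)
#> # A tibble: 4 × 3
#>   instrument label     n
#>   <chr>      <chr> <int>
#> 1 MMSE       RP       35
#> 2 MMSE       nonRP   164
#> 3 MoCA       RP       33
#> 4 MoCA       nonRP   166

# prepare features, rebalance with the hybrid sampler, train, evaluate
g <- run_group(cohort, "MMSE", sampler_config("scus", w_clu = 0.8, seed = 1),
               split_seed = 1, seed = 1)
g$sampling
#> <sampling_result> scus
#>   25 minority + 114 majority -> +89 duplicated rows
g$metrics |> select(sensitivity, f1, auroc, auprc)
#> # A tibble: 1 × 4
#>   sensitivity    f1 auroc auprc
#> 1         0.8 0.889     1     1

# explain the model on held-out patients
att <- attribute_features(g$model,
                          g$x[g$split$train[1:50], , drop = FALSE],
                          g$x[g$split$test, , drop = FALSE])
rank_features(att, 5)
#> # A tibble: 5 × 3
#>    rank feature   importance
#> 1     1 cont_06        0.457
#> 2     2 cat_02=l2      0.360
#> 3     3 cont_01        0.346
#> 4     4 cont_02        0.238
#> 5     5 cont_03        0.227
```

The sampler line reads: the training split held 25 rapid progressors and
114 non-rapid progressors, so 89 minority rows were duplicated (71 chosen by
k-means-centroid proximity, 18 by cosine-similarity ranking at
`w_clu = 0.8`) to reach a 1:1 ratio. On the held-out test patients the model
catches 80% of rapid progressors at the 0.5 threshold and ranks them
perfectly (AUROC 1) in this easy synthetic setting. The attribution table
shows the features driving predictions; `cont_01`–`cont_06` and `cat_01`–
`cat_03` are the generator's informative block, so the ranking recovers
genuinely predictive features.

`run_pipeline()` chains both instrument groups, the stacking ensemble on the
composite group, and attribution into one reproducible report;
`compare_strategies()` re-runs the identical split/model with only the
sampler swapped, and `autoplot()` methods visualize training traces and
importance rankings.

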