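# End-to-end orchestration: label -> prepare -> upsample -> train ->
# evaluate -> explain for one instrument group, the strategy-comparison
# harness, and a full two-instrument pipeline with the stacking ensemble.

#' Train and evaluate one instrument group
#'
#' Labels the cohort's assessments for one instrument, joins the structured
#' features of the labeled patients, splits 70/10/20, fits the feature
#' pipeline on the training rows, upsamples the training set with the chosen
#' strategy, trains the autoencoder classifier, and evaluates on the
#' held-out test rows.
#'
#' @param cohort A `synth_cohort` (or a list with `assessments`, `features`,
#'   `feature_meta`).
#' @param instrument `"MMSE"` or `"MoCA"`.
#' @param sampler A [sampler_config()].
#' @param model_cfg Optional [model_config()] overrides as a named list
#'   (e.g. `list(max_epochs = 40)`); `input_dim` and `seed` are set
#'   internally.
#' @param split_seed Seed for the 70/10/20 split.
#' @param seed Seed for model training.
#' @param threshold Decision threshold for test metrics.
#' @return List with `model`, `pipeline`, `metrics` (one-row tibble),
#'   `split`, `labels`, `probs` (tibble patient_id/prob/label over all
#'   labeled patients), `sampling`.
#' @export
run_group <- function(cohort, instrument, sampler = sampler_config("scus"),
                      model_cfg = list(), split_seed = 1L, seed = 1L,
                      threshold = 0.5) {
  labels <- label_assessments(cohort$assessments) |>
    dplyr::filter(.data$instrument == !!instrument, !.data$excluded)
  if (nrow(labels) < 10) abort_input("too few labeled patients in this group")
  dat <- dplyr::inner_join(labels[c("patient_id", "label")],
                           cohort$features, by = "patient_id")
  y <- as.numeric(dat$label == "RP")
  feats <- dat[setdiff(names(dat), "label")]
  kinds <- setNames(cohort$feature_meta$kind, cohort$feature_meta$column)

  sp <- split_indices(nrow(dat), seed = split_seed)
  fp <- fit_feature_pipeline(feats, y, kinds = kinds, fit_rows = sp$train)
  x_all <- as_feature_matrix(predict(fp, feats))

  res <- upsample(x_all[sp$train, , drop = FALSE], y[sp$train], sampler)

  cfg <- do.call(model_config, modifyList(
    list(input_dim = ncol(x_all), seed = seed), model_cfg))
  model <- fit_rp_model(res$x, res$y,
                        x_all[sp$val, , drop = FALSE], y[sp$val], cfg)

  prob_test <- predict(model, x_all[sp$test, , drop = FALSE])
  metrics <- compute_metrics(y[sp$test], prob_test, threshold)

  probs <- tibble(patient_id = dat$patient_id,
                  prob = predict(model, x_all),
                  label = dat$label)

  list(model = model, pipeline = fp, metrics = metrics, split = sp,
       labels = labels, probs = probs, sampling = res,
       x = x_all, y = y)
}

#' Compare upsampling strategies under identical conditions
#'
#' Runs [run_group()] once per strategy with the same split, feature
#' pipeline inputs, model configuration and seeds, so that only the sampler
#' differs and the test sets are bitwise identical across strategies.
#'
#' @inheritParams run_group
#' @param strategies Character vector of strategy names.
#' @param p_nr,w_clu Sampler parameters shared by all strategies.
#' @param sampler_seed Seed for the samplers.
#' @return Tibble: one metrics row per strategy.
#' @export
compare_strategies <- function(cohort, strategies = c("default", "scus"),
                               instrument = "MMSE", p_nr = 1.0, w_clu = 0.8,
                               sampler_seed = 1L, model_cfg = list(),
                               split_seed = 1L, seed = 1L) {
  if (length(strategies) < 1) abort_config("need at least one strategy")
  purrr::map_dfr(strategies, function(s) {
    sc <- sampler_config(s, p_nr = p_nr, w_clu = w_clu, seed = sampler_seed)
    g <- run_group(cohort, instrument, sampler = sc, model_cfg = model_cfg,
                   split_seed = split_seed, seed = seed)
    dplyr::bind_cols(tibble(strategy = s), g$metrics)
  })
}

#' Full two-instrument pipeline with stacking ensemble and attribution
#'
#' Simulates (or accepts) a cohort, runs [run_group()] for each requested
#' instrument, stacks the per-instrument probabilities on the composite
#' group (patients labeled concordantly under both instruments), fits the
#' logistic ensemble on a seeded 70/30 split inside the composite group, and
#' explains each instrument model with [attribute_features()] over a
#' background of up to 100 training rows.
#'
#' @param cohort A `synth_cohort`; defaults to `simulate_cohort(config)`.
#' @param config A [synth_config()] used when `cohort` is missing.
#' @param sampler A [sampler_config()].
#' @param model_cfg Named-list overrides for [model_config()].
#' @param seed Master seed for split/training/ensemble.
#' @param top_k Top-k depth for feature ranking.
#' @return List with per-instrument group results, `ensemble` (metrics +
#'   coefficients, when both instruments are present), `attribution`
#'   (per-instrument top-k tibbles and max local-accuracy error), and
#'   `report` (a plain, JSON-serializable summary).
#' @export
run_pipeline <- function(cohort = NULL, config = synth_config(),
                         sampler = sampler_config("scus"),
                         model_cfg = list(), seed = 1L, top_k = 10) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  instruments <- intersect(c("MMSE", "MoCA"),
                           unique(cohort$assessments$instrument))

  groups <- purrr::map(setNames(instruments, instruments), function(inst) {
    run_group(cohort, inst, sampler = sampler, model_cfg = model_cfg,
              split_seed = seed, seed = seed)
  })

  ensemble <- NULL
  if (length(instruments) == 2) {
    comp_labels <- resolve_composite(
      dplyr::bind_rows(purrr::map(groups, "labels")))
    stacked <- stack_probabilities(
      groups$MMSE$probs[c("patient_id", "prob")],
      groups$MoCA$probs[c("patient_id", "prob")],
      comp_labels
    )
    if (nrow(stacked) >= 10 && length(unique(stacked$label)) == 2) {
      n <- nrow(stacked)
      tr <- with_seed(seed + 101L, sort(sample(n, round(0.7 * n))))
      te <- setdiff(seq_len(n), tr)
      if (length(unique(stacked$label[tr])) == 2 &&
          length(unique(stacked$label[te])) == 2) {
        st <- fit_stacker(stacked[tr, ])
        pr <- predict(st, stacked[te, ])
        ensemble <- list(
          stacker = st,
          n_composite = n,
          metrics = compute_metrics(pr$label, pr$prob)
        )
      }
    }
  }

  attribution <- purrr::map(groups, function(g) {
    bg_rows <- g$split$train
    if (length(bg_rows) > 100) {
      bg_rows <- with_seed(seed + 202L, sort(sample(bg_rows, 100)))
    }
    rep_ <- attribute_features(g$model, g$x[bg_rows, , drop = FALSE],
                               g$x[g$split$test, , drop = FALSE])
    err <- max(abs(rep_$base_value + rowSums(rep_$attributions) - rep_$output))
    list(report = rep_, top = rank_features(rep_, top_k),
         local_accuracy_error = err)
  })

  report <- list(
    n_patients = nrow(cohort$truth),
    rp_fraction = mean(cohort$truth$label == "RP"),
    groups = purrr::map(groups, function(g) {
      list(n_labeled = nrow(g$labels),
           n_features = ncol(g$x),
           sampling = g$sampling$counts,
           metrics = as.list(g$metrics))
    }),
    ensemble = if (!is.null(ensemble)) {
      list(n_composite = ensemble$n_composite,
           metrics = as.list(ensemble$metrics))
    },
    top_features = purrr::map(attribution, function(a) as.list(a$top)),
    attribution_error = purrr::map_dbl(attribution, "local_accuracy_error")
  )

  list(cohort = cohort, groups = groups, ensemble = ensemble,
       attribution = attribution, report = report)
}
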