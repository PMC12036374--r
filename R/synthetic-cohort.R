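#' Configuration for the synthetic EHR cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' the study conditions the pipeline is designed for: an imbalanced
#' dementia cohort (about 18% rapid progressors), longitudinal MMSE/MoCA
#' score timelines with a clear separation between rapid and non-rapid
#' decline rates, mixed continuous/categorical structured features with
#' missingness, and clinical-note snippets embedding the scores.
#'
#' Rapid progressors decline at rates drawn uniformly from
#' `decline_rate_rp` (points/year) and non-rapid patients from
#' `decline_rate_nonrp`; both supports must sit strictly on their side of
#' `label_threshold` so that ground-truth labels are recoverable by
#' [label_assessments()]. With the default gaps (330-480 days between
#' successive assessments) the worst-case perturbation from integer score
#' rounding is about 1.1 points/year, inside the >= 1.5 point margin the
#' default rate supports leave to the threshold.
#'
#' @param n_patients Number of patients.
#' @param rp_prevalence Fraction of patients that are rapid progressors.
#' @param instruments Character subset of `c("MMSE", "MoCA")`.
#' @param n_continuous,n_categorical Numbers of structured feature columns.
#' @param informative_fraction Fraction of each feature block whose
#'   distribution differs between classes.
#' @param effect_size Standardized mean shift of informative continuous
#'   features between classes (also tilts informative categorical levels).
#' @param missing_rate Completely-at-random missingness fraction applied to
#'   the feature table.
#' @param assessments_per_patient Integer range `c(min, max)` of assessments
#'   per patient and instrument; patients drawing 1 exercise the
#'   single-record exclusion.
#' @param followup_gap_days Integer range of days between successive
#'   assessments.
#' @param decline_rate_rp,decline_rate_nonrp Uniform `c(min, max)` supports
#'   of the true decline rate (points/year) per class.
#' @param baseline_score_range Range of the (integer) baseline score.
#' @param noise_sd Gaussian sd (points) of trajectory noise. Noise is applied
#'   to assessments other than the baseline and the qualifying target, which
#'   stay on the rounded linear trajectory so that the generated label is
#'   exactly recoverable.
#' @param label_threshold Decline rate (points/year) at or above which a
#'   patient is a rapid progressor.
#' @param min_gap_days Minimum baseline-to-target gap used to pick the anchor
#'   target assessment (mirrors the labeling default).
#' @param both_instrument_fraction When both instruments are requested, the
#'   fraction of patients assessed with both (the composite group).
#' @param seed Integer seed; the same config yields byte-identical cohorts.
#'
#' @return An object of class `synth_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
synth_config <- function(n_patients = 500,
                         rp_prevalence = 0.18,
                         instruments = c("MMSE", "MoCA"),
                         n_continuous = 20,
                         n_categorical = 10,
                         informative_fraction = 0.3,
                         effect_size = 1.0,
                         missing_rate = 0.10,
                         assessments_per_patient = c(2L, 5L),
                         followup_gap_days = c(330L, 480L),
                         decline_rate_rp = c(4.5, 7.5),
                         decline_rate_nonrp = c(-0.5, 1.4),
                         baseline_score_range = c(20L, 28L),
                         noise_sd = 1,
                         label_threshold = 3,
                         min_gap_days = 183L,
                         both_instrument_fraction = 0.3,
                         seed = 1L) {
  assert_count(n_patients, "n_patients", positive = TRUE)
  assert_fraction(rp_prevalence, "rp_prevalence")
  assert_fraction(informative_fraction, "informative_fraction")
  assert_fraction(missing_rate, "missing_rate", allow_one = FALSE)
  assert_fraction(both_instrument_fraction, "both_instrument_fraction")
  instruments <- match.arg(instruments, c("MMSE", "MoCA"), several.ok = TRUE)
  assert_count(n_continuous, "n_continuous")
  assert_count(n_categorical, "n_categorical")
  if (length(assessments_per_patient) != 2 ||
      assessments_per_patient[1] > assessments_per_patient[2] ||
      assessments_per_patient[1] < 1) {
    abort_config("`assessments_per_patient` must be an increasing range >= 1")
  }
  if (length(followup_gap_days) != 2 || followup_gap_days[1] > followup_gap_days[2] ||
      followup_gap_days[1] < 1) {
    abort_config("`followup_gap_days` must be an increasing positive range")
  }
  if (min(decline_rate_rp) <= label_threshold) {
    abort_config("`decline_rate_rp` support must lie strictly above `label_threshold`")
  }
  if (max(decline_rate_nonrp) >= label_threshold) {
    abort_config("`decline_rate_nonrp` support must lie strictly below `label_threshold`")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0")
  cfg <- list(
    n_patients = as.integer(n_patients),
    rp_prevalence = rp_prevalence,
    instruments = instruments,
    n_continuous = as.integer(n_continuous),
    n_categorical = as.integer(n_categorical),
    informative_fraction = informative_fraction,
    effect_size = effect_size,
    missing_rate = missing_rate,
    assessments_per_patient = as.integer(assessments_per_patient),
    followup_gap_days = as.integer(followup_gap_days),
    decline_rate_rp = decline_rate_rp,
    decline_rate_nonrp = decline_rate_nonrp,
    baseline_score_range = as.integer(baseline_score_range),
    noise_sd = noise_sd,
    label_threshold = label_threshold,
    min_gap_days = as.integer(min_gap_days),
    both_instrument_fraction = both_instrument_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}

# One linear score timeline for one patient x instrument. The baseline and the
# first assessment at least `min_gap_days` later (the anchor target) carry no
# trajectory noise, so the observed decline rate stays within rounding error
# of the true rate and the generated class is recoverable.
simulate_timeline <- function(cfg, rate) {
  n <- sample(cfg$assessments_per_patient[1]:cfg$assessments_per_patient[2], 1)
  gaps <- sample(cfg$followup_gap_days[1]:cfg$followup_gap_days[2], n, replace = TRUE)
  offsets <- cumsum(c(0L, gaps[-1]))
  start <- as.Date("2014-01-01") + sample(0:1460, 1)
  dates <- start + offsets
  base <- sample(cfg$baseline_score_range[1]:cfg$baseline_score_range[2], 1)
  years <- offsets / 365.25
  scores <- base - rate * years
  anchor_target <- if (n >= 2) which(offsets >= cfg$min_gap_days)[1] else NA_integer_
  noisy <- setdiff(seq_len(n), c(1L, anchor_target))
  if (length(noisy) > 0 && cfg$noise_sd > 0) {
    scores[noisy] <- scores[noisy] + rnorm(length(noisy), 0, cfg$noise_sd)
  }
  scores <- round(pmin(30, pmax(0, scores)))
  tibble(date = dates, score = as.integer(scores))
}

simulate_features <- function(cfg, cls) {
  n <- cfg$n_patients
  out <- list()
  meta <- list()
  n_inf_c <- round(cfg$informative_fraction * cfg$n_continuous)
  for (j in seq_len(cfg$n_continuous)) {
    mu <- runif(1, -5, 5)
    s <- runif(1, 0.8, 2)
    shift <- if (j <= n_inf_c) cfg$effect_size else 0
    nm <- sprintf("cont_%02d", j)
    out[[nm]] <- mu + s * (rnorm(n) + shift * cls)
    meta[[nm]] <- "continuous"
  }
  n_inf_k <- round(cfg$informative_fraction * cfg$n_categorical)
  for (j in seq_len(cfg$n_categorical)) {
    L <- sample(2:5, 1)
    base_p <- rgamma(L, 1)
    base_p <- base_p / sum(base_p)
    if (j <= n_inf_k) {
      tilt <- exp(cfg$effect_size * seq(-0.7, 0.7, length.out = L))
      alt_p <- base_p * tilt
      alt_p <- alt_p / sum(alt_p)
    } else {
      alt_p <- base_p
    }
    levels <- paste0("l", seq_len(L))
    vals <- character(n)
    vals[cls == 0] <- sample(levels, sum(cls == 0), replace = TRUE, prob = base_p)
    vals[cls == 1] <- sample(levels, sum(cls == 1), replace = TRUE, prob = alt_p)
    nm <- sprintf("cat_%02d", j)
    out[[nm]] <- vals
    meta[[nm]] <- "categorical"
  }
  features <- as_tibble(out)
  if (cfg$missing_rate > 0 && ncol(features) > 0) {
    mask <- matrix(runif(n * ncol(features)) < cfg$missing_rate, nrow = n)
    for (j in seq_along(features)) {
      features[[j]][mask[, j]] <- NA
    }
  }
  list(
    features = features,
    meta = tibble(column = names(meta), kind = unname(unlist(meta)))
  )
}

#' Generate a synthetic EHR cohort
#'
#' Draws a reproducible cohort with per-patient cognitive-assessment
#' timelines, structured features, clinical-note snippets, and ground-truth
#' rapid-progression labels. Patient classes are Bernoulli draws at
#' `rp_prevalence`; each patient's timelines decline linearly at a rate drawn
#' from the class-specific support, plus Gaussian noise on non-anchor
#' assessments, with integer rounding and clipping to the 0-30 instrument
#' range.
#'
#' @param config A [synth_config()] object.
#' @param templates Note templates passed to [render_notes()].
#' @return An object of class `synth_cohort`: a list with elements
#'   `assessments` (tibble: patient_id, date, instrument, score), `notes`
#'   (tibble: patient_id, date, text), `features` (tibble with `patient_id`),
#'   `feature_meta` (tibble: column, kind), `truth` (tibble: patient_id,
#'   label) and `config`.
#' @examples
#' cohort <- simulate_cohort(synth_config(n_patients = 40, seed = 7))
#' dplyr::count(cohort$truth, label)
#' @export
simulate_cohort <- function(config = synth_config(),
                            templates = default_note_templates()) {
  if (!inherits(config, "synth_config")) {
    abort_config("`config` must be created with synth_config()")
  }
  cfg <- config
  with_seed(cfg$seed, {
    ids <- sprintf("P%04d", seq_len(cfg$n_patients))
    cls <- rbinom(cfg$n_patients, 1, cfg$rp_prevalence)

    if (length(cfg$instruments) == 2) {
      u <- runif(cfg$n_patients)
      both <- u < cfg$both_instrument_fraction
      pick <- ifelse(runif(cfg$n_patients) < 0.5, "MMSE", "MoCA")
      inst_list <- lapply(seq_len(cfg$n_patients), function(i) {
        if (both[i]) cfg$instruments else pick[i]
      })
    } else {
      inst_list <- rep(list(cfg$instruments), cfg$n_patients)
    }

    assessments <- purrr::map_dfr(seq_len(cfg$n_patients), function(i) {
      purrr::map_dfr(inst_list[[i]], function(inst) {
        rng <- if (cls[i] == 1) cfg$decline_rate_rp else cfg$decline_rate_nonrp
        rate <- runif(1, rng[1], rng[2])
        tl <- simulate_timeline(cfg, rate)
        tibble(patient_id = ids[i], date = tl$date,
               instrument = inst, score = tl$score)
      })
    })

    feats <- simulate_features(cfg, cls)
    features <- dplyr::bind_cols(tibble(patient_id = ids), feats$features)

    notes <- render_notes(assessments, templates,
                          seed = cfg$seed + 1L)

    structure(
      list(
        assessments = assessments,
        notes = notes,
        features = features,
        feature_meta = feats$meta,
        truth = tibble(patient_id = ids,
                       label = ifelse(cls == 1, "RP", "nonRP")),
        config = cfg
      ),
      class = "synth_cohort"
    )
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort>\n")
  cat("  patients:   ", nrow(x$truth),
      sprintf(" (%d RP / %d nonRP)\n",
              sum(x$truth$label == "RP"), sum(x$truth$label == "nonRP")))
  cat("  assessments:", nrow(x$assessments), "\n")
  cat("  features:   ", ncol(x$features) - 1, "columns\n")
  invisible(x)
}

#' Default clinical-note templates
#'
#' Each template must contain both a `{instrument}` and a `{score}`
#' placeholder; [render_notes()] rejects templates missing either. The bank
#' is deliberately varied so that the round-trip with [extract_scores()]
#' exercises several phrasings.
#'
#' @return Character vector of templates.
#' @export
default_note_templates <- function() {
  c(
    "{instrument} score: {score}/30.",
    "Cognitive testing today: {instrument} {score}/30; follow up in 6 months.",
    "{instrument}: {score} points. Patient accompanied by spouse.",
    "The patient scored {score} on the {instrument} this visit.",
    "{instrument} was {score} today; medications reviewed.",
    "Repeat {instrument} performed, score of {score}."
  )
}

#' Render clinical-note snippets from assessment records
#'
#' Produces one note per assessment by substituting the instrument and score
#' into a randomly chosen template.
#'
#' @param assessments Tibble with columns `patient_id`, `date`, `instrument`,
#'   `score`.
#' @param templates Character templates containing `{instrument}` and
#'   `{score}` placeholders.
#' @param seed Integer seed for template choice.
#' @return Tibble with columns `patient_id`, `date`, `text`.
#' @export
render_notes <- function(assessments, templates = default_note_templates(),
                         seed = 1L) {
  bad <- !grepl("\\{instrument\\}", templates) | !grepl("\\{score\\}", templates)
  if (any(bad)) {
    abort_config("every template needs both {instrument} and {score} placeholders")
  }
  if (nrow(assessments) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  text = character()))
  }
  with_seed(seed, {
    idx <- sample(seq_along(templates), nrow(assessments), replace = TRUE)
    text <- purrr::map_chr(seq_len(nrow(assessments)), function(i) {
      t <- templates[idx[i]]
      t <- gsub("{instrument}", assessments$instrument[i], t, fixed = TRUE)
      gsub("{score}", assessments$score[i], t, fixed = TRUE)
    })
    tibble(patient_id = assessments$patient_id,
           date = assessments$date, text = text)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `assessments.csv`, `notes.jsonl`, `features.csv`,
#' `feature_meta.json` and `truth.csv` into `dir`.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$assessments, file.path(dir, "assessments.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "notes.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort$notes))) {
    writeLines(jsonlite::toJSON(
      list(patient_id = cohort$notes$patient_id[i],
           date = as.character(cohort$notes$date[i]),
           text = cohort$notes$text[i]),
      auto_unbox = TRUE), con)
  }
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$feature_meta, file.path(dir, "feature_meta.json"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
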