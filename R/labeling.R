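#' ICD code filters for Alzheimer's disease and related dementias
#'
#' Exact (non-prefix) ICD-9/ICD-10 code sets for the four disease groups the
#' cohort definition covers. Matching is exact string match on normalized
#' (uppercase, whitespace-stripped) codes because child codes are enumerated
#' explicitly.
#'
#' @return Tibble with columns `disease_group`, `system` (icd9/icd10), `code`.
#' @export
dementia_icd_filters <- function() {
  groups <- list(
    AD = list(icd9 = "331.0",
              icd10 = c("G30", "G30.0", "G30.1", "G30.8", "G30.9")),
    vascular = list(icd9 = c("290.4", "290.40", "290.41", "290.42", "290.43"),
                    icd10 = c("F01", "F01.5", "F01.50", "F01.51")),
    lewy_body = list(icd9 = "331.82", icd10 = "G31.83"),
    frontotemporal = list(icd9 = c("331.1", "331.11", "331.19"),
                          icd10 = c("G31.0", "G31.01", "G31.09"))
  )
  purrr::map_dfr(names(groups), function(g) {
    dplyr::bind_rows(
      tibble(disease_group = g, system = "icd9", code = groups[[g]]$icd9),
      tibble(disease_group = g, system = "icd10", code = groups[[g]]$icd10)
    )
  })
}

normalize_code <- function(code) toupper(gsub("\\s+", "", code))

#' Retain patients matching diagnosis code filters
#'
#' A patient is retained iff any of their codes appears in any filter's code
#' set (exact match on normalized codes).
#'
#' @param patient_codes Tibble with columns `patient_id`, `code`.
#' @param filters Tibble as returned by [dementia_icd_filters()].
#' @return Tibble with columns `patient_id`, `disease_group` (first matching
#'   group per patient), one row per retained patient.
#' @export
filter_diagnosis <- function(patient_codes, filters = dementia_icd_filters()) {
  if (is.null(filters) || nrow(filters) == 0) {
    abort_config("`filters` must contain at least one code")
  }
  filters <- dplyr::mutate(filters, code = normalize_code(.data$code))
  patient_codes |>
    dplyr::mutate(code = normalize_code(.data$code)) |>
    dplyr::inner_join(filters, by = "code", relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(disease_group = dplyr::first(.data$disease_group),
                     .groups = "drop")
}

#' Select baseline and target assessments for one patient and instrument
#'
#' Applies the cohort exclusion rules: a single record excludes the patient;
#' with two records the second must fall at least `min_gap_days` after the
#' first; with more than two, the earliest record is the baseline and the
#' earliest follow-up at least `min_gap_days` later is the target. Same-day
#' duplicates are collapsed to the lower score first (conservative,
#' deterministic). The result is invariant to input ordering.
#'
#' @param records Tibble with columns `date`, `score` (one patient, one
#'   instrument).
#' @param min_gap_days Minimum baseline-to-target gap in days (default 183,
#'   i.e. six months).
#' @return A list with either `pair` (tibble: index_date, score_base,
#'   target_date, score_target) and `reason = NA`, or `pair = NULL` and a
#'   `reason` in `c("single_record", "gap_too_short", "no_qualifying_followup")`.
#' @export
select_baseline_target <- function(records, min_gap_days = 183) {
  if (nrow(records) == 0) abort_input("`records` must contain at least one row")
  rec <- records |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(score = min(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$date)
  n <- nrow(rec)
  if (n == 1) {
    return(list(pair = NULL, reason = "single_record"))
  }
  gaps <- as.numeric(rec$date - rec$date[1])
  qual <- which(gaps >= min_gap_days)
  if (length(qual) == 0) {
    reason <- if (n == 2) "gap_too_short" else "no_qualifying_followup"
    return(list(pair = NULL, reason = reason))
  }
  t <- qual[1]
  list(
    pair = tibble(index_date = rec$date[1], score_base = rec$score[1],
                  target_date = rec$date[t], score_target = rec$score[t]),
    reason = NA_character_
  )
}

#' Cognitive decline rate in points per year
#'
#' `(score_base - score_target) / elapsed years`, with years = days/365.25.
#' Positive rates are decline; negative rates indicate improvement.
#'
#' @param pair Tibble with columns `index_date`, `score_base`, `target_date`,
#'   `score_target` (as from [select_baseline_target()]).
#' @return Numeric rate in points/year.
#' @export
progression_rate <- function(pair) {
  days <- as.numeric(as.Date(pair$target_date) - as.Date(pair$index_date))
  if (any(days <= 0)) abort_input("target_date must be after index_date")
  (pair$score_base - pair$score_target) / (days / 365.25)
}

#' Assign a rapid-progression label from a decline rate
#'
#' A patient is a rapid progressor when the decline rate reaches `threshold`
#' points/year. By default the comparison is inclusive (`>=`) for both
#' instruments; `strict_moca = TRUE` switches MoCA to a strict `>` comparison.
#'
#' @param rate Decline rate(s), points/year.
#' @param instrument `"MMSE"` or `"MoCA"` (vectorized).
#' @param threshold Rate threshold, default 3 points/year.
#' @param strict_moca Use strict inequality for MoCA.
#' @return Character vector, `"RP"` or `"nonRP"`.
#' @export
assign_label <- function(rate, instrument, threshold = 3, strict_moca = FALSE) {
  if (any(!is.finite(rate))) abort_input("`rate` must be finite")
  strict <- strict_moca & instrument == "MoCA"
  ifelse(ifelse(strict, rate > threshold, rate >= threshold), "RP", "nonRP")
}

#' Label a cohort's assessment records
#'
#' Runs baseline/target selection, decline-rate computation and labeling per
#' patient and instrument, with full exclusion accounting: every input
#' patient x instrument appears exactly once, either labeled or excluded with
#' a reason.
#'
#' @param assessments Tibble with columns `patient_id`, `date`, `instrument`,
#'   `score`.
#' @param min_gap_days,threshold,strict_moca See [select_baseline_target()]
#'   and [assign_label()].
#' @return Tibble with columns `patient_id`, `instrument`, `index_date`,
#'   `target_date`, `score_base`, `score_target`, `p_rate`, `label`,
#'   `excluded`, `reason`.
#' @examples
#' cohort <- simulate_cohort(synth_config(n_patients = 30, seed = 2))
#' labels <- label_assessments(cohort$assessments)
#' dplyr::count(labels, instrument, label, reason)
#' @export
label_assessments <- function(assessments, min_gap_days = 183, threshold = 3,
                              strict_moca = FALSE) {
  bad <- assessments$score < 0 | assessments$score > 30
  if (any(bad, na.rm = TRUE)) abort_input("scores must lie in 0-30")
  assessments |>
    dplyr::group_by(.data$patient_id, .data$instrument) |>
    dplyr::group_modify(function(df, key) {
      sel <- select_baseline_target(df, min_gap_days = min_gap_days)
      if (is.null(sel$pair)) {
        return(tibble(index_date = as.Date(NA), target_date = as.Date(NA),
                      score_base = NA_integer_, score_target = NA_integer_,
                      p_rate = NA_real_, label = NA_character_,
                      excluded = TRUE, reason = sel$reason))
      }
      rate <- progression_rate(sel$pair)
      dplyr::bind_cols(
        sel$pair,
        tibble(p_rate = rate,
               label = assign_label(rate, key$instrument, threshold,
                                    strict_moca),
               excluded = FALSE, reason = NA_character_)
      )
    }) |>
    dplyr::ungroup()
}

#' Resolve the composite group across two instruments
#'
#' Retains patients labeled (not excluded) under both instruments with
#' identical labels; patients with conflicting labels or present in only one
#' group are dropped.
#'
#' @param labels Label tibble from [label_assessments()] covering both
#'   instruments (or two such tibbles row-bound).
#' @return Tibble with columns `patient_id`, `label`.
#' @export
resolve_composite <- function(labels) {
  labels |>
    dplyr::filter(!.data$excluded) |>
    dplyr::distinct(.data$patient_id, .data$instrument, .keep_all = TRUE) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n_distinct(.data$instrument) == 2,
                  dplyr::n_distinct(.data$label) == 1) |>
    dplyr::summarise(label = dplyr::first(.data$label), .groups = "drop")
}
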