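#' Default pattern bank for cognitive-score extraction
#'
#' A documented, user-extensible set of Perl-compatible regular expressions
#' used by [extract_scores()]. Each pattern must contain two named capture
#' groups: `instrument` (matching MMSE or MoCA, case-insensitively) and
#' `score` (1-2 digits). Users can extend the bank by concatenating their own
#' patterns; extraction applies every pattern and de-duplicates hits that
#' start at the same text position.
#'
#' @return Character vector of PCRE patterns.
#' @export
default_score_patterns <- function() {
  inst <- "(?<instrument>MMSE|MoCA)"
  score <- "(?<score>\\d{1,2})"
  c(
    # "MMSE score: 24/30", "MoCA: 22 points", "MMSE 27/30", "MMSE was 22"
    paste0(inst, "\\s*(?:score)?\\s*[:=]?\\s*(?:was|is|of)?\\s*", score,
           "(?:\\s*/\\s*30)?"),
    # "scored 24 on the MMSE"
    paste0("scored\\s+", score, "\\s+on\\s+the\\s+", inst),
    # "score of 24 ... MMSE" within the same clause, e.g. "MMSE performed, score of 24"
    paste0(inst, "\\s+performed,\\s+score\\s+of\\s+", score)
  )
}

#' Extract cognitive scores from clinical-note text
#'
#' Applies a rule-based pattern bank to each note and emits one assessment
#' record per match. Scores outside the 0-30 instrument range are discarded;
#' notes with unparseable dates are skipped with a warning.
#'
#' @param notes Tibble with columns `patient_id`, `date`, `text`.
#' @param patterns Pattern bank; see [default_score_patterns()].
#' @return Tibble with columns `patient_id`, `date`, `instrument`, `score`,
#'   one row per extracted score.
#' @examples
#' notes <- tibble::tibble(patient_id = "P1", date = as.Date("2020-01-01"),
#'                         text = "MoCA was 22 today; prior MMSE 27/30")
#' extract_scores(notes)
#' @export
extract_scores <- function(notes, patterns = default_score_patterns()) {
  empty <- tibble(patient_id = character(), date = as.Date(character()),
                  instrument = character(), score = integer())
  if (nrow(notes) == 0) return(empty)

  dates <- if (inherits(notes$date, "Date")) {
    notes$date
  } else {
    vapply(as.character(notes$date), function(d) {
      out <- tryCatch(suppressWarnings(as.Date(d)),
                      error = function(e) as.Date(NA))
      as.numeric(out)
    }, numeric(1), USE.NAMES = FALSE) |> as.Date(origin = "1970-01-01")
  }

  out <- purrr::map_dfr(seq_len(nrow(notes)), function(i) {
    if (is.na(dates[i])) {
      warn(sprintf("skipping note %d: unparseable date '%s'",
                   i, as.character(notes$date[i])))
      return(NULL)
    }
    hits <- purrr::map_dfr(patterns, function(p) {
      m <- stringr::str_match_all(notes$text[i], stringr::regex(p, ignore_case = TRUE))[[1]]
      if (nrow(m) == 0) return(NULL)
      loc <- stringr::str_locate_all(notes$text[i],
                                     stringr::regex(p, ignore_case = TRUE))[[1]]
      tibble(
        instrument = m[, "instrument"],
        score = suppressWarnings(as.integer(m[, "score"])),
        start = loc[, 1]
      )
    })
    if (nrow(hits) == 0) return(NULL)
    hits <- hits[!duplicated(hits$start), , drop = FALSE]
    hits <- hits[!is.na(hits$score) & hits$score >= 0 & hits$score <= 30, ,
                 drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    tibble(
      patient_id = notes$patient_id[i],
      date = dates[i],
      instrument = ifelse(toupper(hits$instrument) == "MMSE", "MMSE", "MoCA"),
      score = hits$score
    )
  })
  if (nrow(out) == 0) empty else out
}
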