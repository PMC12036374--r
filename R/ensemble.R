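# Two-instrument stacking ensemble: the predicted probabilities of the
# MMSE-based and MoCA-based models on composite-group patients are joined
# into a two-column feature vector and fed to a logistic regression.

#' Stack per-instrument predicted probabilities
#'
#' Inner-joins the two probability tables on `patient_id`; column order is
#' fixed as `(p_mmse, p_moca)`.
#'
#' @param probs_mmse,probs_moca Tibbles with columns `patient_id`, `prob`.
#' @param labels Tibble with columns `patient_id`, `label` ("RP"/"nonRP" or
#'   0/1).
#' @return Tibble with `patient_id`, `p_mmse`, `p_moca`, `label` (0/1).
#' @export
stack_probabilities <- function(probs_mmse, probs_moca, labels) {
  joined <- dplyr::inner_join(
    dplyr::rename(probs_mmse, p_mmse = "prob"),
    dplyr::rename(probs_moca, p_moca = "prob"),
    by = "patient_id"
  )
  if (nrow(joined) == 0) abort_input("no patients shared between the two models")
  lab <- labels
  if (is.character(lab$label)) {
    lab <- dplyr::mutate(lab, label = as.numeric(.data$label == "RP"))
  }
  dplyr::inner_join(joined, lab, by = "patient_id")
}

#' Fit the stacked logistic ensemble
#'
#' Maximum-likelihood logistic regression of the label on the two base-model
#' probabilities (two weights plus intercept, unregularized).
#'
#' @param features Tibble from [stack_probabilities()].
#' @return Object of class `rp_stacker` wrapping the `glm` fit.
#' @export
fit_stacker <- function(features) {
  if (length(unique(features$label)) < 2) {
    abort_input("both classes must be present to fit the stacker")
  }
  fit <- suppressWarnings(
    glm(label ~ p_mmse + p_moca, family = binomial(), data = features))
  structure(list(fit = fit), class = "rp_stacker")
}

#' Predict with the stacked ensemble
#'
#' @param object An `rp_stacker`.
#' @param newdata Tibble with `p_mmse`, `p_moca` (and optionally
#'   `patient_id`).
#' @param threshold Decision threshold, default 0.5.
#' @param ... Unused.
#' @return Input tibble with added `prob` and `pred` (0/1) columns.
#' @export
predict.rp_stacker <- function(object, newdata, threshold = 0.5, ...) {
  prob <- as.numeric(predict(object$fit, newdata = newdata, type = "response"))
  dplyr::mutate(as_tibble(newdata), prob = prob,
                pred = as.integer(prob >= threshold))
}

#' @export
print.rp_stacker <- function(x, ...) {
  cat("<rp_stacker> logit(p) =",
      paste(sprintf("%.3f", stats::coef(x$fit)), collapse = " + "), "\n")
  invisible(x)
}

#' @rdname fit_stacker
#' @param x An `rp_stacker`.
#' @param ... Unused.
#' @method tidy rp_stacker
#' @export
tidy.rp_stacker <- function(x, ...) {
  co <- stats::coef(x$fit)
  tibble(term = names(co), estimate = unname(co))
}
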