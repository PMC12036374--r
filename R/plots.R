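# ggplot2 visualisations for the main result types.

#' Plot the training trace of a fitted model
#'
#' Training and validation total loss per epoch, with the best epoch marked.
#'
#' @param object A fitted `rp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rp_model
#' @export
autoplot.rp_model <- function(object, ...) {
  df <- object$trace |>
    dplyr::select("epoch", "train_total", "val_total") |>
    tidyr::pivot_longer(-"epoch", names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = ifelse(.data$set == "train_total",
                               "training", "validation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "total loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of top attributed features
#'
#' Mean absolute attribution of the top-k features, mirroring the usual
#' SHAP importance bar layout.
#'
#' @param object An `rp_attribution`.
#' @param k Top-k depth (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rp_attribution
#' @export
autoplot.rp_attribution <- function(object, k = 10, ...) {
  top <- rank_features(object, k)
  ggplot2::ggplot(top, ggplot2::aes(.data$importance,
                                    stats::reorder(.data$feature,
                                                   .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |attribution|", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot metrics across upsampling strategies
#'
#' @param comparison Tibble from [compare_strategies()].
#' @return A ggplot object (one facet per metric).
#' @export
plot_strategy_comparison <- function(comparison) {
  df <- comparison |>
    dplyr::select("strategy", "sensitivity", "f1", "auroc", "auprc") |>
    tidyr::pivot_longer(-"strategy", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$strategy, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
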